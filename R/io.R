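#' Read a cell table
#'
#' CSV with one row per cell: positions `x`, `y`, `z` (micrometres) plus
#' either polarity-tensor component columns (`xx, xy, xz, yy, yz, zz`) or
#' tripod axis columns (`nx..lz`), or both. Missing required columns are
#' reported by name; rows with missing or non-numeric entries are reported
#' with their line numbers.
#'
#' @param path CSV file path.
#' @return A validated tibble (an `id` column is added when absent).
#' @export
read_cells <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(tab) == 0L) stop("no records in ", path, call. = FALSE)
  pos <- c("x", "y", "z")
  tensor_cols <- c("xx", "xy", "xz", "yy", "yz", "zz")
  tripod_cols <- c("nx", "ny", "nz", "mx", "my", "mz", "lx", "ly", "lz")
  miss <- setdiff(pos, names(tab))
  if (length(miss) > 0L) {
    stop("cells file missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  has_tensor <- all(tensor_cols %in% names(tab))
  has_tripod <- all(tripod_cols %in% names(tab))
  if (!has_tensor && !has_tripod) {
    stop("cells file needs tensor columns (", paste(tensor_cols, collapse = ", "),
         ") or tripod columns (", paste(tripod_cols, collapse = ", "), ")",
         call. = FALSE)
  }
  used <- c(pos, if (has_tensor) tensor_cols, if (has_tripod) tripod_cols)
  bad <- which(!stats::complete.cases(tab[used]))
  if (length(bad) > 0L) {
    stop("malformed rows at lines ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "),
         if (length(bad) > 5L) " ...", " of ", path, call. = FALSE)
  }
  if (!"id" %in% names(tab)) tab$id <- seq_len(nrow(tab))
  tab
}

#' Read a segment table
#'
#' Accepts either an edge list (`x1, y1, z1, x2, y2, z2`, converted via
#' [segments_from_edges()]) or precomputed midpoint/direction/length columns
#' (`mx..mz`, `dx..dz`, `length`).
#'
#' @param path CSV file path.
#' @return A validated segment-set tibble.
#' @export
read_segments <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(tab) == 0L) stop("no records in ", path, call. = FALSE)
  if (all(c("x1", "y1", "z1", "x2", "y2", "z2") %in% names(tab))) {
    return(segments_from_edges(tab))
  }
  validate_segments(tab)
}

#' Write a spherical decomposition / power spectrum / tensor as JSON
#'
#' Decompositions are stored as records `(l, m, re, im)` with the band limit
#' and normalization convention; spectra as records `(l, power)`; nematic
#' tensors with their matrix, ordered eigenvalues, axes and degeneracy flags.
#'
#' @param decomp A `sph_decomp`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_decomp_json <- function(decomp, path) {
  jsonlite::write_json(list(
    lmax = decomp$lmax, convention = decomp$convention,
    coefficients = tidy.sph_decomp(decomp)), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decomp_json
#' @export
read_decomp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- obj$coefficients
  coef <- complex(real = tab$re, imaginary = tab$im)
  idx <- lm_index(tab$l, tab$m)
  out <- complex(length.out = (obj$lmax + 1)^2)
  out[idx] <- coef
  structure(list(lmax = as.integer(obj$lmax), coef = out,
                 convention = obj$convention), class = "sph_decomp")
}

#' @rdname write_decomp_json
#' @param spectrum A `sph_power_spectrum` tibble.
#' @export
write_spectrum_json <- function(spectrum, path) {
  jsonlite::write_json(as.data.frame(spectrum), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decomp_json
#' @param tensor A `nematic_tensor`.
#' @export
write_tensor_json <- function(tensor, path) {
  ax <- ordered_axes(tensor)
  jsonlite::write_json(list(
    matrix = unclass(tensor),
    eigenvalues = list(alpha1 = ax$alpha1, alpha3 = ax$alpha3,
                       alpha2 = ax$alpha2),
    axes = list(a1 = ax$a1, a3 = ax$a3, a2 = ax$a2),
    degenerate = ax$degenerate, degenerate_pairs = ax$degenerate_pairs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decomp_json
#' @param result A `coop_result` or `oop_result`.
#' @export
write_order_json <- function(result, path) {
  obj <- list(estimates = result$estimates, n = result$n)
  if (inherits(result, "coop_result")) obj$dropped <- result$dropped
  if (inherits(result, "oop_result")) {
    obj$pi_perm <- result$pi_perm
    obj$rho_perm <- result$rho_perm
    obj$co_diagonalizable <- result$co_diagonalizable
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
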
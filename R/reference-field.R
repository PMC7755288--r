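#' Local reference field from a punctured Gaussian kernel
#'
#' For each cell `i` with position `x_i` and nematic tensor `A_i`, the local
#' reference tensor is the kernel-weighted average of the *other* cells'
#' tensors,
#' \eqn{E_i = \sum_{j \ne i} k(|x_j - x_i|) A_j / \sum_{j \ne i} k(|x_j - x_i|)},
#' with a Gaussian kernel of standard deviation `sigma` truncated at
#' `4 sigma`. Excluding the central cell ("puncturing") makes the reference
#' independent of the measured object. Reference tripods follow the
#' `eps1 >= eps3 >= eps2` ordering (`w = e2`, `v = e1`, `u = e3`), which makes
#' the frame robust under curved director fields.
#'
#' @param cells Tibble with positions `x`, `y`, `z` (micrometres) and tensor
#'   component columns `xx, xy, xz, yy, yz, zz`.
#' @param sigma Kernel standard deviation (micrometres).
#' @param truncate Kernel support radius in units of `sigma`.
#' @param degeneracy_tol Relative tolerance flagging degenerate local tensors.
#' @return A reference-tripod tibble (columns `wx..uz`) with the averaged
#'   tensor components (`xx..zz`) and logical flags `isolated` (no neighbour
#'   inside the kernel support) and `degenerate`.
#' @export
local_reference_field <- function(cells, sigma = 20, truncate = 4,
                                  degeneracy_tol = 1e-6) {
  stopifnot(sigma > 0)
  need <- c("x", "y", "z", "xx", "xy", "xz", "yy", "yz", "zz")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0L) {
    stop("cells table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(cells)
  if (n < 2L) stop("need at least 2 cells", call. = FALSE)
  pos <- cbind(cells$x, cells$y, cells$z)
  d2 <- as.matrix(stats::dist(pos))^2
  K <- exp(-d2 / (2 * sigma^2))
  K[d2 > (truncate * sigma)^2] <- 0
  diag(K) <- 0  # puncture: omit the central cell
  rs <- rowSums(K)
  isolated <- rs < 1e-12
  rs[isolated] <- 1
  A_cols <- as.matrix(cells[, c("xx", "xy", "xz", "yy", "yz", "zz")])
  E_cols <- (K / rs) %*% A_cols
  E_tab <- tibble::as_tibble(as.data.frame(E_cols))
  names(E_tab) <- c("xx", "xy", "xz", "yy", "yz", "zz")
  refs <- reference_frames_from_tensors(E_tab, degeneracy_tol = degeneracy_tol)
  refs <- dplyr::bind_cols(refs, E_tab)
  refs$isolated <- isolated
  refs$degenerate <- refs$degenerate | isolated
  if (any(isolated)) {
    message(sum(isolated), " isolated cells flagged (no neighbour within ",
            truncate, " sigma)")
  }
  refs
}

#' OOP/COOP continuity diagnostic along a parameter path
#'
#' Evaluates both the classical order parameters ([oop()]) and the
#' co-orientational order parameters ([coop()]) for a parameterized family of
#' ensembles. COOP change continuously along smooth paths, whereas OOP jump by
#' O(1) where the selected axis permutation switches; this table makes the
#' contrast measurable.
#'
#' @param family A function `function(parameter)` returning a list with
#'   elements `tripods` (tripod tibble) and `references` (reference-tripod
#'   tibble, one row or one per tripod).
#' @param parameters Numeric vector of path points.
#' @return A tibble with one row per path point: `parameter`, OOP columns
#'   `S`, `P`, `D`, `C`, and COOP columns `co_S`, `co_P`, `co_D`, `co_C`.
#' @export
continuity_diagnostic <- function(family, parameters) {
  purrr::map_dfr(parameters, function(t) {
    ens <- family(t)
    o <- oop(ens$tripods, n_boot = 0L)
    cc <- coop(ens$tripods, ens$references, n_boot = 0L)
    dplyr::bind_cols(
      tibble::tibble(parameter = t),
      tibble::as_tibble(as.list(stats::setNames(o$estimates$value,
                                                o$estimates$parameter))),
      tibble::as_tibble(as.list(stats::setNames(cc$estimates$value,
                                                cc$estimates$parameter))))
  })
}
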
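#' Segment sets
#'
#' A segment set describes a network of straight centerline segments as a
#' tibble with midpoint columns `mx`, `my`, `mz` (micrometres), unit direction
#' columns `dx`, `dy`, `dz` (sign-free) and `length` (micrometres).
#' [segments_from_edges()] builds one from an edge list of endpoints.
#'
#' @param edges Data frame with endpoint columns `x1, y1, z1, x2, y2, z2`.
#' @return A segment-set tibble.
#' @export
segments_from_edges <- function(edges) {
  need <- c("x1", "y1", "z1", "x2", "y2", "z2")
  miss <- setdiff(need, names(edges))
  if (length(miss) > 0L) {
    stop("edge list missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- cbind(edges$x2 - edges$x1, edges$y2 - edges$y1, edges$z2 - edges$z1)
  len <- sqrt(rowSums(d^2))
  if (any(len <= 0)) stop("zero-length segments", call. = FALSE)
  tibble::tibble(
    mx = (edges$x1 + edges$x2) / 2, my = (edges$y1 + edges$y2) / 2,
    mz = (edges$z1 + edges$z2) / 2,
    dx = d[, 1] / len, dy = d[, 2] / len, dz = d[, 3] / len,
    length = len)
}

validate_segments <- function(segments) {
  need <- c("mx", "my", "mz", "dx", "dy", "dz", "length")
  miss <- setdiff(need, names(segments))
  if (length(miss) > 0L) {
    stop("segment set missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nrm <- segments$dx^2 + segments$dy^2 + segments$dz^2
  if (nrow(segments) > 0L && max(abs(nrm - 1)) > 1e-8) {
    stop("segment directions must be unit vectors", call. = FALSE)
  }
  if (any(segments$length <= 0)) stop("segment lengths must be > 0", call. = FALSE)
  segments
}

#' Local anisotropy tensor of a segment network
#'
#' Length-weighted nematic tensor of the segment directions inside a
#' spherical region of interest,
#' \eqn{S = \sum_k w_k l_k (d_k \otimes d_k - \tfrac13 1)} with binary weights
#' \eqn{w} selecting segments whose *midpoint* lies within `radius` of
#' `center`, normalized so \eqn{\sum_k w_k l_k = 1}. Eigen-axes: `s1`
#' (largest eigenvalue) is the preferred segment orientation, `s2` (smallest)
#' the normal of the plane in which segments are preferentially distributed
#' (the layer normal of a layered network), `s3 = s1 x s2`.
#'
#' @param segments A segment-set tibble (see [segments_from_edges()]).
#' @param center Length-3 numeric, region-of-interest center (micrometres).
#' @param radius Region-of-interest radius (micrometres).
#' @return A list of class `network_anisotropy`: `tensor` (`nematic_tensor`),
#'   unit axes `s1`, `s2`, `s3` (sign-free), `n_segments`, `degenerate` flag
#'   (in-plane isotropy: `s1` undetermined).
#' @export
network_tensor <- function(segments, center = c(0, 0, 0), radius = 20) {
  validate_segments(segments)
  stopifnot(radius > 0, length(center) == 3L)
  d2 <- (segments$mx - center[1])^2 + (segments$my - center[2])^2 +
    (segments$mz - center[3])^2
  inr <- d2 <= radius^2
  if (!any(inr)) stop("empty neighborhood: no segment midpoint within radius",
                      call. = FALSE)
  seg <- segments[inr, ]
  w <- seg$length / sum(seg$length)
  dmat <- cbind(seg$dx, seg$dy, seg$dz)
  S <- crossprod(dmat, dmat * w) - diag(3) / 3
  S <- as_nematic_tensor((S + t(S)) / 2)
  ax <- ordered_axes(S)
  structure(list(
    tensor = S,
    s1 = ax$a1, s2 = ax$a2, s3 = canonical_sign(row_cross(matrix(ax$a1, 1),
                                                          matrix(ax$a2, 1))[1, ]),
    eigenvalues = c(s1 = ax$alpha1, s3 = ax$alpha3, s2 = ax$alpha2),
    n_segments = nrow(seg),
    degenerate = ax$degenerate
  ), class = "network_anisotropy")
}

#' @export
print.network_anisotropy <- function(x, ...) {
  cat("<network_anisotropy>", x$n_segments, "segments; eigenvalues (s1, s3, s2):",
      paste(signif(x$eigenvalues, 4), collapse = ", "),
      if (x$degenerate) " [degenerate]", "\n")
  invisible(x)
}

#' Network anisotropy at many centers
#'
#' Evaluates [network_tensor()] in a spherical region of interest around each
#' center (e.g. each cell position). Centers with empty neighborhoods are
#' flagged rather than erroring, so downstream analyses can exclude them.
#'
#' @inheritParams network_tensor
#' @param centers Data frame with columns `x`, `y`, `z`.
#' @return A tibble with one row per center: tensor components `xx..zz`, axis
#'   columns `s1x..s3z`, `n_segments`, logical `empty` and `degenerate`.
#' @export
network_field <- function(segments, centers, radius = 20) {
  validate_segments(segments)
  purrr::map_dfr(seq_len(nrow(centers)), function(i) {
    ctr <- c(centers$x[i], centers$y[i], centers$z[i])
    res <- tryCatch(network_tensor(segments, ctr, radius), error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(xx = NA_real_, xy = NA_real_, xz = NA_real_,
                            yy = NA_real_, yz = NA_real_, zz = NA_real_,
                            s1x = NA_real_, s1y = NA_real_, s1z = NA_real_,
                            s2x = NA_real_, s2y = NA_real_, s2z = NA_real_,
                            s3x = NA_real_, s3y = NA_real_, s3z = NA_real_,
                            n_segments = 0L, empty = TRUE, degenerate = NA))
    }
    m <- unclass(res$tensor)
    tibble::tibble(xx = m[1, 1], xy = m[1, 2], xz = m[1, 3],
                   yy = m[2, 2], yz = m[2, 3], zz = m[3, 3],
                   s1x = res$s1[1], s1y = res$s1[2], s1z = res$s1[3],
                   s2x = res$s2[1], s2y = res$s2[2], s2z = res$s2[3],
                   s3x = res$s3[1], s3y = res$s3[2], s3z = res$s3[3],
                   n_segments = res$n_segments, empty = FALSE,
                   degenerate = res$degenerate)
  })
}
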
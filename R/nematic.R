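#' Nematic tensor of a surface pattern
#'
#' The symmetric traceless second-moment tensor
#' \eqn{A = \frac12 \sum_k w_k v_k (3\, d_k \otimes d_k - 1)} of the density on
#' the unit sphere. `A` carries exactly the information of the second
#' spherical-harmonic mode: adding odd-mode or `l = 3` content to the density
#' leaves it unchanged.
#'
#' @inheritParams validate_surface_pattern
#' @return A 3x3 symmetric traceless matrix of class `nematic_tensor` (units
#'   of total pattern mass).
#' @export
nematic_tensor <- function(pattern) {
  validate_surface_pattern(pattern)
  d <- pattern_directions(pattern)
  wv <- pattern$weight * pattern$value
  second <- crossprod(d, d * wv)  # sum wv d d^T
  A <- 0.5 * (3 * second - sum(wv) * diag(3))
  A <- (A + t(A)) / 2
  if (max(abs(A)) < 1e-14 * max(1, sum(abs(wv)))) {
    warning("isotropic/empty pattern: zero nematic tensor", call. = FALSE)
  }
  as_nematic_tensor(A)
}

#' Coerce a matrix to a nematic tensor
#'
#' Validates symmetry and tracelessness (both within 1e-8 of the matrix
#' scale) and attaches the `nematic_tensor` class.
#'
#' @param m A 3x3 numeric matrix.
#' @return The matrix with class `nematic_tensor`.
#' @export
as_nematic_tensor <- function(m) {
  m <- unclass(m)
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  tol <- 1e-10 + 1e-8 * max(abs(m))
  if (max(abs(m - t(m))) > tol) stop("tensor not symmetric", call. = FALSE)
  if (abs(sum(diag(m))) > tol) stop("tensor not traceless", call. = FALSE)
  structure(m, class = c("nematic_tensor", "matrix", "array"))
}

#' @export
print.nematic_tensor <- function(x, ...) {
  cat("<nematic_tensor>\n")
  print(unclass(x), ...)
  invisible(x)
}

canonical_sign <- function(v, tol = 1e-12) {
  nz <- which(abs(v) > tol)
  if (length(nz) == 0L) return(v)
  if (v[nz[1]] < 0) -v else v
}

#' Ordered eigen-system of a nematic tensor
#'
#' Eigenvalues are labelled `alpha1 >= alpha3 >= alpha2` with eigenvectors
#' `a1` (bipolar axis, largest eigenvalue, smallest moment of inertia), `a2`
#' (ring axis, smallest eigenvalue, largest moment of inertia) and `a3`.
#' Axes are nematic (sign-free); the stored representative has its first
#' non-zero component positive. Near-degenerate eigenvalue pairs (within
#' `tol * ||A||`) are flagged; ties are broken by the deterministic order of
#' the underlying symmetric eigen-solver followed by sign canonicalization.
#'
#' @param tensor A `nematic_tensor` (or plain symmetric traceless 3x3 matrix).
#' @param tol Relative degeneracy tolerance.
#' @return A list of class `nematic_axes` with `alpha1`, `alpha2`, `alpha3`,
#'   unit axes `a1`, `a2`, `a3`, and `degenerate` (logical) plus
#'   `degenerate_pairs` (character).
#' @export
ordered_axes <- function(tensor, tol = 1e-8) {
  m <- unclass(as_nematic_tensor(tensor))
  es <- eigen(m, symmetric = TRUE)  # decreasing eigenvalues
  scale <- max(abs(es$values), 1e-300)
  pairs <- character(0)
  if (abs(es$values[1] - es$values[2]) <= tol * scale) pairs <- c(pairs, "alpha1-alpha3")
  if (abs(es$values[2] - es$values[3]) <= tol * scale) pairs <- c(pairs, "alpha3-alpha2")
  structure(list(
    alpha1 = es$values[1], alpha3 = es$values[2], alpha2 = es$values[3],
    a1 = canonical_sign(es$vectors[, 1]),
    a3 = canonical_sign(es$vectors[, 2]),
    a2 = canonical_sign(es$vectors[, 3]),
    degenerate = length(pairs) > 0L,
    degenerate_pairs = pairs
  ), class = "nematic_axes")
}

#' @export
print.nematic_axes <- function(x, ...) {
  cat("<nematic_axes> alpha1 =", signif(x$alpha1, 5),
      " alpha3 =", signif(x$alpha3, 5),
      " alpha2 =", signif(x$alpha2, 5),
      if (x$degenerate) paste0(" [degenerate: ",
                               paste(x$degenerate_pairs, collapse = ", "), "]"),
      "\n")
  cat("  a1 (bipolar):", paste(signif(x$a1, 4), collapse = ", "), "\n")
  cat("  a2 (ring):   ", paste(signif(x$a2, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy nematic axes into a tibble
#'
#' @param x A `nematic_axes` object.
#' @param ... Unused.
#' @return A tibble with one row per axis: `axis`, `eigenvalue`, `x`, `y`, `z`.
#' @export
tidy.nematic_axes <- function(x, ...) {
  tibble::tibble(
    axis = c("a1", "a3", "a2"),
    role = c("bipolar", "intermediate", "ring"),
    eigenvalue = c(x$alpha1, x$alpha3, x$alpha2),
    x = c(x$a1[1], x$a3[1], x$a2[1]),
    y = c(x$a1[2], x$a3[2], x$a2[2]),
    z = c(x$a1[3], x$a3[3], x$a2[3])
  )
}

#' Rebuild a nematic tensor from its eigen-system
#'
#' \eqn{A = \sum_i \alpha_i\, a_i \otimes a_i} for an orthonormal axis tripod
#' and eigenvalues summing to zero. Round-trips with [ordered_axes()].
#'
#' @param a1,a2,a3 Orthonormal unit 3-vectors (sign-free).
#' @param alpha Length-3 numeric `c(alpha1, alpha2, alpha3)` summing to 0
#'   within 1e-8 of its scale.
#' @return A `nematic_tensor`.
#' @export
tensor_from_axes <- function(a1, a2, a3, alpha) {
  V <- cbind(a1, a2, a3)
  if (max(abs(crossprod(V) - diag(3))) > 1e-6) {
    stop("axes must be orthonormal", call. = FALSE)
  }
  if (abs(sum(alpha)) > 1e-8 * max(1, max(abs(alpha)))) {
    stop("eigenvalues must sum to zero", call. = FALSE)
  }
  A <- alpha[1] * tcrossprod(a1) + alpha[2] * tcrossprod(a2) +
    alpha[3] * tcrossprod(a3)
  as_nematic_tensor((A + t(A)) / 2)
}

#' Traceless moments-of-inertia tensor of a pattern
#'
#' The traceless part of \eqn{\sum_k w_k v_k (|d_k|^2 1 - d_k \otimes d_k)};
#' on the unit sphere this equals \eqn{-\tfrac23 A}, so the axis of largest
#' nematic eigenvalue is the axis of smallest moment of inertia.
#'
#' @inheritParams validate_surface_pattern
#' @return A `nematic_tensor`.
#' @export
traceless_inertia <- function(pattern) {
  A <- nematic_tensor(pattern)
  as_nematic_tensor(-(2 / 3) * unclass(A))
}

#' Equivalent cuboid of a nematic tensor
#'
#' The solid cuboid whose traceless moments-of-inertia tensor matches that of
#' the spherical distribution (\eqn{-\tfrac23 A}). Matching the full second
#' moment of a unit-sphere distribution of the given mass yields squared
#' half-lengths \eqn{h_i^2 = 1 + 2\alpha_i/\textrm{mass}}; half-lengths are
#' then rescaled to unit volume (unit longest edge if a side is zero), since
#' only shape ratios and orientation are meaningful. The longest edge is
#' parallel to the bipolar axis `a1`, the shortest to the ring axis `a2`.
#'
#' @param tensor A `nematic_tensor`.
#' @param mass Total pattern mass the tensor was computed from.
#' @return A list of class `cuboid_rep`: `half_lengths` (named by axis, order
#'   a1, a3, a2), `rotation` (columns a1, a3, a2; face colors red, green,
#'   blue), `axes` (the [ordered_axes()]), `degenerate` flag.
#' @export
equivalent_cuboid <- function(tensor, mass = 1) {
  stopifnot(mass > 0)
  ax <- ordered_axes(tensor)
  h2 <- 1 + 2 * c(ax$alpha1, ax$alpha3, ax$alpha2) / mass
  if (any(h2 < -1e-9)) {
    stop("not cuboid-representable: requires alpha_i/mass >= -1/2, got ",
         signif(min(c(ax$alpha1, ax$alpha3, ax$alpha2)) / mass, 4), call. = FALSE)
  }
  h <- sqrt(pmax(0, h2))
  vol <- prod(2 * h)
  h <- if (vol > 1e-12) h / vol^(1 / 3) else h / max(h)
  structure(list(
    half_lengths = stats::setNames(h, c("a1", "a3", "a2")),
    rotation = cbind(a1 = ax$a1, a3 = ax$a3, a2 = ax$a2),
    face_colors = c(a1 = "red", a3 = "green", a2 = "blue"),
    axes = ax, degenerate = ax$degenerate
  ), class = "cuboid_rep")
}

#' @export
print.cuboid_rep <- function(x, ...) {
  cat("<cuboid_rep> half lengths (a1, a3, a2):",
      paste(signif(x$half_lengths, 4), collapse = ", "),
      if (x$degenerate) " [degenerate]", "\n")
  invisible(x)
}
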
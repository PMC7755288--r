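#' Axis-tripod ensembles
#'
#' A tripod ensemble is a tibble with one row per object and nine columns:
#' the first principal axis `n` (`nx`, `ny`, `nz`), the second `m`
#' (`mx`, `my`, `mz`) and the third `l` (`lx`, `ly`, `lz`). Axes are nematic
#' (defined up to sign, D2h symmetry): every order parameter computed from a
#' tripod ensemble is invariant under sign flips of any axis. Reference-tripod
#' tibbles use columns `wx..wz` (first reference axis), `vx..vz` (second),
#' `ux..uz` (third).
#'
#' @param n,m,l Numeric matrices (rows = objects, 3 columns) of unit axes;
#'   `l` defaults to the completion `n x m`.
#' @return A tibble with columns `nx..lz`.
#' @export
tripod_ensemble <- function(n, m, l = NULL) {
  n <- as_axis_matrix(n); m <- as_axis_matrix(m)
  if (is.null(l)) l <- row_cross(n, m) else l <- as_axis_matrix(l)
  out <- tibble::tibble(
    nx = n[, 1], ny = n[, 2], nz = n[, 3],
    mx = m[, 1], my = m[, 2], mz = m[, 3],
    lx = l[, 1], ly = l[, 2], lz = l[, 3])
  validate_tripods(out)
}

#' Reference-tripod tibble
#'
#' @param w,v,u Numeric matrices (rows = objects, 3 columns) of the first,
#'   second and third reference axes; `u` defaults to `v x w`.
#' @return A tibble with columns `wx..uz`.
#' @export
reference_tripods <- function(w, v, u = NULL) {
  w <- as_axis_matrix(w); v <- as_axis_matrix(v)
  if (is.null(u)) u <- row_cross(v, w) else u <- as_axis_matrix(u)
  tibble::tibble(
    wx = w[, 1], wy = w[, 2], wz = w[, 3],
    vx = v[, 1], vy = v[, 2], vz = v[, 3],
    ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

as_axis_matrix <- function(a) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3, byrow = TRUE)
  a <- as.matrix(a)
  stopifnot(ncol(a) == 3L)
  a / sqrt(rowSums(a^2))
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Validate a tripod-ensemble tibble
#'
#' Checks unit norms and pairwise orthogonality (within 1e-6).
#'
#' @param tripods A tibble with columns `nx..lz`.
#' @return The validated tibble, unchanged.
#' @export
validate_tripods <- function(tripods) {
  need <- c("nx", "ny", "nz", "mx", "my", "mz", "lx", "ly", "lz")
  miss <- setdiff(need, names(tripods))
  if (length(miss) > 0L) {
    stop("tripod ensemble missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tripods) == 0L) stop("empty tripod ensemble", call. = FALSE)
  axes <- tripod_axes(tripods)
  for (a in axes) {
    if (max(abs(rowSums(a^2) - 1)) > 1e-6) {
      stop("tripod axes must be unit vectors", call. = FALSE)
    }
  }
  dots <- pmax(abs(rowSums(axes$n * axes$m)),
               abs(rowSums(axes$n * axes$l)),
               abs(rowSums(axes$m * axes$l)))
  if (max(dots) > 1e-6) stop("tripod axes must be orthogonal", call. = FALSE)
  tripods
}

tripod_axes <- function(tripods) {
  list(n = cbind(tripods$nx, tripods$ny, tripods$nz),
       m = cbind(tripods$mx, tripods$my, tripods$mz),
       l = cbind(tripods$lx, tripods$ly, tripods$lz))
}

reference_axes <- function(refs) {
  list(w = cbind(refs$wx, refs$wy, refs$wz),
       v = cbind(refs$vx, refs$vy, refs$vz),
       u = cbind(refs$ux, refs$uy, refs$uz))
}

#' Q and B tensors of a single tripod
#'
#' The two traceless tensors characterizing a D2h tripod:
#' \eqn{Q = \frac12(3 n \otimes n - 1)} (eigenvalues 1, -1/2, -1/2) and
#' \eqn{B = \frac32(l \otimes l - m \otimes m)} (eigenvalues 3/2, -3/2, 0).
#' Both are invariant under sign flips of the axes.
#'
#' @param n,m,l Orthonormal unit 3-vectors.
#' @return A list with matrices `Q` and `B`.
#' @export
qb_tensors <- function(n, m, l) {
  n <- n / sqrt(sum(n^2)); m <- m / sqrt(sum(m^2)); l <- l / sqrt(sum(l^2))
  list(Q = 0.5 * (3 * tcrossprod(n) - diag(3)),
       B = 1.5 * (tcrossprod(l) - tcrossprod(m)))
}

# ensemble averages <Q>, <B> for a tripod tibble
mean_qb <- function(tripods) {
  ax <- tripod_axes(tripods)
  n <- ax$n; m <- ax$m; l <- ax$l
  k <- nrow(n)
  Q <- 0.5 * (3 * crossprod(n) / k - diag(3))
  B <- 1.5 * (crossprod(l) - crossprod(m)) / k
  list(Q = (Q + t(Q)) / 2, B = (B + t(B)) / 2)
}
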
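#' Surface patterns on the unit sphere
#'
#' A *surface pattern* is a weighted sample of a density `f` on the unit
#' sphere: a tibble with columns `x`, `y`, `z` (unit direction vectors),
#' `weight` (solid-angle quadrature weight, steradian) and `value` (density at
#' that direction, mass per steradian). Patterns come from radial projection of
#' a labelled cell surface ([project_to_sphere()]) or from the synthetic
#' generators ([synth_pattern()]). All downstream operations
#' ([sph_decompose()], [nematic_tensor()], ...) take this tibble first so that
#' calls chain with the pipe.
#'
#' @param x,y,z Numeric vectors of unit direction components.
#' @param weight Non-negative quadrature weights (steradian).
#' @param value Density values at each direction.
#' @return A tibble with columns `x`, `y`, `z`, `weight`, `value`.
#' @examples
#' g <- sphere_grid_gauss(8)
#' p <- surface_pattern(g$x, g$y, g$z, g$weight, value = 1)
#' sum(p$weight * p$value) / (4 * pi)
#' @export
surface_pattern <- function(x, y, z, weight, value) {
  pat <- tibble::tibble(x = x, y = y, z = z,
                        weight = weight, value = value)
  validate_surface_pattern(pat)
}

#' Validate a surface-pattern tibble
#'
#' Checks the pattern invariants: direction norms equal to 1 (within 1e-12 of
#' squared norm 1), non-negative weights, no missing values.
#'
#' @param pattern A pattern tibble (see [surface_pattern()]).
#' @return The validated pattern, invisibly unchanged.
#' @export
validate_surface_pattern <- function(pattern) {
  need <- c("x", "y", "z", "weight", "value")
  miss <- setdiff(need, names(pattern))
  if (length(miss) > 0L) {
    stop("pattern is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pattern) == 0L) stop("no samples", call. = FALSE)
  nrm2 <- pattern$x^2 + pattern$y^2 + pattern$z^2
  if (any(abs(nrm2 - 1) > 1e-10)) {
    stop("directions must be unit vectors (max |r^2 - 1| = ",
         format(max(abs(nrm2 - 1))), ")", call. = FALSE)
  }
  if (any(pattern$weight < 0)) stop("weights must be >= 0", call. = FALSE)
  if (anyNA(pattern[need])) stop("pattern contains NA", call. = FALSE)
  pattern
}

pattern_directions <- function(pattern) {
  cbind(pattern$x, pattern$y, pattern$z)
}

#' Total mass of a pattern
#'
#' The solid-angle integral of the density, `sum(weight * value)`.
#'
#' @inheritParams validate_surface_pattern
#' @return A scalar.
#' @export
pattern_mass <- function(pattern) {
  sum(pattern$weight * pattern$value)
}

#' Gauss--Legendre product grid on the sphere
#'
#' Quadrature nodes that integrate band-limited functions exactly:
#' Gauss--Legendre nodes in the cosine of the colatitude crossed with a uniform
#' longitude grid. With `lmax = L` the grid uses `L + 1` colatitudes and
#' `2L + 1` longitudes, which integrates products of two degree-`L`
#' band-limited functions exactly, so Parseval residuals for band-limited
#' patterns vanish to rounding error.
#'
#' @param lmax Band limit the grid must resolve exactly (integer >= 0).
#' @return A tibble with columns `x`, `y`, `z`, `weight`; weights sum to 4*pi.
#' @seealso [sphere_grid_fibonacci()] for an equal-area grid.
#' @export
sphere_grid_gauss <- function(lmax) {
  stopifnot(lmax >= 0)
  n_theta <- lmax + 1L
  n_phi <- 2L * lmax + 1L
  gl <- pracma::gaussLegendre(max(n_theta, 2L), -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  ct <- rep(gl$x, each = n_phi)
  w <- rep(gl$w, each = n_phi) * (2 * pi / n_phi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = length(gl$x))
  tibble::tibble(x = st * cos(ph), y = st * sin(ph), z = ct, weight = w)
}

#' Fibonacci equal-area grid on the sphere
#'
#' `n` points of a Fibonacci spiral lattice, each carrying the equal-area
#' weight `4*pi/n`. The quadrature is approximate (use
#' [sphere_grid_gauss()] when exact band-limited integration is required) but
#' the nodes are evenly spread, which mimics irregular mesh-projected samples.
#'
#' @param n Number of nodes.
#' @return A tibble with columns `x`, `y`, `z`, `weight`.
#' @export
sphere_grid_fibonacci <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1L)
  st <- sqrt(pmax(0, 1 - z^2))
  tibble::tibble(x = st * cos(phi), y = st * sin(phi), z = z,
                 weight = rep(4 * pi / n, n))
}

#' Read / write surface-pattern CSV files
#'
#' Plain CSV with header `x,y,z,weight,value`.
#'
#' @param path File path.
#' @return `read_pattern()` returns a validated pattern tibble.
#' @export
read_pattern <- function(path) {
  pat <- readr::read_csv(path, show_col_types = FALSE)
  validate_surface_pattern(pat)
}

#' @rdname read_pattern
#' @inheritParams validate_surface_pattern
#' @export
write_pattern <- function(pattern, path) {
  validate_surface_pattern(pattern)
  readr::write_csv(pattern, path)
  invisible(path)
}
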
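#' Spherical-harmonic decomposition of a surface pattern
#'
#' Expands the density carried by a pattern into spherical-harmonic modes
#' \eqn{f(x) = \sum_l F_l(x)}, \eqn{F_l = \sum_m f_{lm} Y_{lm}}, with
#' coefficients computed as the quadrature form of the sphere inner product
#' \eqn{f_{lm} = \sum_k w_k v_k \bar Y_{lm}(d_k)}. Harmonics are complex,
#' orthonormal, with Condon--Shortley phase, so that for real densities
#' \eqn{f_{l,-m} = (-1)^m \bar f_{lm}}.
#'
#' @inheritParams validate_surface_pattern
#' @param lmax Band limit `L >= 0`. A warning (not an error) is given when
#'   `lmax` exceeds what the sample count can resolve.
#' @return An object of class `sph_decomp`: a list with `lmax`, complex
#'   `coef` (length `(L+1)^2`, flat index `l^2 + l + m + 1`) and the
#'   normalization tag `convention = "orthonormal_condon_shortley"`.
#' @examples
#' g <- sphere_grid_gauss(8)
#' d <- surface_pattern(g$x, g$y, g$z, g$weight, 1) |> sph_decompose(4)
#' Mod(d$coef[1]) # sqrt(4*pi) for f == 1
#' @export
sph_decompose <- function(pattern, lmax = 16L) {
  validate_surface_pattern(pattern)
  stopifnot(lmax >= 0)
  lmax <- as.integer(lmax)
  if ((lmax + 1L)^2 > nrow(pattern)) {
    warning("band limit ", lmax, " exceeds what ", nrow(pattern),
            " samples can resolve", call. = FALSE)
  }
  dirs <- pattern_directions(pattern)
  wv <- pattern$weight * pattern$value
  coef <- complex(length.out = (lmax + 1L)^2)
  ylm_visit(dirs, lmax, function(l, Y) {
    idx <- lm_index(l, -l:l)
    coef[idx] <<- as.vector(crossprod(Conj(Y), wv))
  })
  structure(list(lmax = lmax, coef = coef,
                 convention = "orthonormal_condon_shortley"),
            class = "sph_decomp")
}

#' @export
print.sph_decomp <- function(x, ...) {
  cat("<sph_decomp> band limit L =", x$lmax,
      "(", length(x$coef), "coefficients,", x$convention, ")\n")
  invisible(x)
}

#' Tidy a spherical decomposition into a coefficient tibble
#'
#' @param x A `sph_decomp` object.
#' @param ... Unused.
#' @return A tibble with columns `l`, `m`, `re`, `im`.
#' @export
tidy.sph_decomp <- function(x, ...) {
  out <- lm_table(x$lmax)
  out$re <- Re(x$coef)
  out$im <- Im(x$coef)
  out
}

#' Spherical power spectrum
#'
#' The rotation-invariant power of each mode,
#' \eqn{\|F_l\|^2 = (4\pi)^{-1} \sum_m |f_{lm}|^2}
#' (squared L2 norm of the mode, normalized by the sphere area). A dominant
#' `l = 1` classifies a pattern as vectorial, a dominant `l = 2` (among
#' `l >= 1`) as nematic.
#'
#' @param decomp A `sph_decomp` object.
#' @return A tibble with columns `l`, `power`, class `sph_power_spectrum`.
#' @export
sph_power_spectrum <- function(decomp) {
  stopifnot(inherits(decomp, "sph_decomp"))
  tab <- lm_table(decomp$lmax)
  pw <- vapply(0:decomp$lmax, function(l) {
    sum(Mod(decomp$coef[lm_index(l, -l:l)])^2) / (4 * pi)
  }, numeric(1))
  out <- tibble::tibble(l = 0:decomp$lmax, power = pw)
  class(out) <- c("sph_power_spectrum", class(out))
  out
}

#' Squared L2 norm of a pattern
#'
#' \eqn{\|f\|^2 = (4\pi)^{-1} \sum_k w_k v_k^2}, the quadrature form of the
#' sphere-averaged squared density.
#'
#' @inheritParams validate_surface_pattern
#' @return A scalar.
#' @export
pattern_power <- function(pattern) {
  sum(pattern$weight * pattern$value^2) / (4 * pi)
}

#' Parseval residual
#'
#' Absolute difference between the total pattern power \eqn{\|f\|^2} and the
#' summed mode powers \eqn{\sum_l \|F_l\|^2}. For a band-limited pattern
#' sampled on an adequate quadrature grid the residual is at rounding level;
#' for patterns with spectral content above the band limit it equals the
#' truncated tail power.
#'
#' @inheritParams validate_surface_pattern
#' @param decomp The decomposition computed from `pattern`.
#' @return A non-negative scalar.
#' @export
parseval_residual <- function(pattern, decomp) {
  abs(pattern_power(pattern) - sum(sph_power_spectrum(decomp)$power))
}

#' Evaluate a band-limited reconstruction at given directions
#'
#' Sums the modes of a decomposition at the supplied unit directions; the
#' imaginary part (rounding noise for real inputs) is dropped.
#'
#' @param decomp A `sph_decomp` object.
#' @param directions A data frame with columns `x`, `y`, `z` (unit vectors).
#' @return A numeric vector of reconstructed density values.
#' @export
sph_reconstruct <- function(decomp, directions) {
  stopifnot(inherits(decomp, "sph_decomp"))
  dirs <- cbind(directions$x, directions$y, directions$z)
  acc <- complex(length.out = nrow(dirs))
  ylm_visit(dirs, decomp$lmax, function(l, Y) {
    acc <<- acc + as.vector(Y %*% decomp$coef[lm_index(l, -l:l)])
  })
  Re(acc)
}

#' Mollweide map coordinates
#'
#' Equal-area pseudocylindrical projection of unit directions, used to draw
#' sphere maps of surface patterns. The auxiliary angle is solved by Newton
#' iteration; the map ellipse has semi-axes \eqn{2\sqrt2} and \eqn{\sqrt2},
#' so map area equals sphere area and the projection is exactly equal-area.
#'
#' @param directions A data frame with columns `x`, `y`, `z` (unit vectors).
#' @return A tibble with map coordinates `mx`, `my` and the longitude
#'   `lon` / latitude `lat` (radians) they derive from.
#' @export
mollweide_coords <- function(directions) {
  lon <- atan2(directions$y, directions$x)
  lat <- asin(pmin(1, pmax(-1, directions$z)))
  theta <- lat
  target <- pi * sin(lat)
  for (i in 1:50) {
    f <- 2 * theta + sin(2 * theta) - target
    fp <- 2 + 2 * cos(2 * theta)
    step <- ifelse(fp > 1e-12, f / fp, 0)
    theta <- theta - step
    if (max(abs(step)) < 1e-14) break
  }
  # poles: fp -> 0, theta -> +-pi/2 exactly
  theta[abs(abs(lat) - pi / 2) < 1e-12] <- sign(lat[abs(abs(lat) - pi / 2) < 1e-12]) * pi / 2
  tibble::tibble(
    mx = 2 * sqrt(2) / pi * lon * cos(theta),
    my = sqrt(2) * sin(theta),
    lon = lon, lat = lat
  )
}
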
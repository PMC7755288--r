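#' Synthetic surface patterns
#'
#' Prototype marker distributions on the unit sphere, normalized to total
#' mass 1: `cap` (a von Mises--Fisher bump at +z, the vectorial-polarity
#' prototype), `ring` (a Watson girdle around the equator), `bipolar` (a
#' Watson bipolar density, two antipodal bumps at +-z), `uniform`, and
#' `mixture` (equal-mass cap + ring). `concentration = Inf` yields singular
#' idealizations (point caps, a delta ring on equally spaced equator nodes)
#' whose nematic tensors take their closed-form values exactly; these carry
#' nominal weights and are not full-sphere quadratures.
#'
#' @param kind One of `"cap"`, `"ring"`, `"bipolar"`, `"uniform"`,
#'   `"mixture"`.
#' @param concentration Positive spread parameter (von Mises--Fisher /
#'   Watson kappa); `Inf` gives the singular idealization.
#' @param grid Quadrature grid tibble (`x`, `y`, `z`, `weight`); default
#'   [sphere_grid_gauss()] with band limit 48.
#' @param n_ideal Number of nodes for the singular ring idealization.
#' @return A surface-pattern tibble with total mass 1.
#' @export
synth_pattern <- function(kind = c("cap", "ring", "bipolar", "uniform", "mixture"),
                          concentration = 4, grid = sphere_grid_gauss(48),
                          n_ideal = 360L) {
  kind <- match.arg(kind)
  stopifnot(concentration > 0)
  if (is.infinite(concentration)) {
    return(ideal_pattern(kind, n_ideal))
  }
  k <- concentration
  vals <- switch(kind,
    cap = exp(k * (grid$z - 1)),
    ring = exp(-k * grid$z^2),
    bipolar = exp(k * (grid$z^2 - 1)),
    uniform = rep(1, nrow(grid)),
    mixture = exp(k * (grid$z - 1)) + exp(-k * grid$z^2))
  pat <- surface_pattern(grid$x, grid$y, grid$z, grid$weight, vals)
  pat$value <- pat$value / pattern_mass(pat)
  pat
}

ideal_pattern <- function(kind, n_ideal) {
  switch(kind,
    cap = surface_pattern(0, 0, 1, weight = 1, value = 1),
    bipolar = surface_pattern(c(0, 0), c(0, 0), c(1, -1),
                              weight = c(1, 1), value = c(0.5, 0.5)),
    ring = {
      phi <- 2 * pi * (seq_len(n_ideal) - 1L) / n_ideal
      surface_pattern(cos(phi), sin(phi), rep(0, n_ideal),
                      weight = rep(1 / n_ideal, n_ideal),
                      value = rep(1, n_ideal))
    },
    stop("no singular idealization for kind '", kind, "'", call. = FALSE))
}

# inverse-CDF sample of cos(theta) for a von Mises-Fisher density around +z
rvmf_costheta <- function(n, kappa) {
  u <- stats::runif(n)
  if (kappa < 1e-8) return(2 * u - 1)
  1 + log1p(-u * (1 - exp(-2 * kappa))) / kappa
}

# rejection sample angles from p(psi) ~ exp(b * cos(2*(psi - psi0)))
rbimodal_angle <- function(n, b, psi0 = 0) {
  if (b < 1e-12) return(stats::runif(n, 0, 2 * pi))
  out <- numeric(0)
  while (length(out) < n) {
    batch <- max(2L * (n - length(out)), 64L)
    psi <- stats::runif(batch, 0, 2 * pi)
    keep <- log(stats::runif(batch)) < b * (cos(2 * (psi - psi0)) - 1)
    out <- c(out, psi[keep])
  }
  out[seq_len(n)]
}

#' Synthetic tripod ensembles with prescribed co-orientational order
#'
#' Generates the six prototype biaxial distributions against a fixed
#' reference frame (`w`, `v`, `u`; default the coordinate axes z, x, y):
#' \describe{
#'   \item{`prolate`}{first axis `n` clustered around `w`; second axis free
#'     (`co_S > 0`, `co_D = co_C = 0`).}
#'   \item{`phase_biaxial`}{`n` clustered around `w` with fluctuations biased
#'     towards `u` (`co_S > 0`, `co_P > 0`).}
#'   \item{`oblate`}{`n` scattered near the plane normal to `w`
#'     (`co_S < 0`, girdle order).}
#'   \item{`prolate_free`}{alias of `prolate` (tripod view of the same
#'     ensemble).}
#'   \item{`molecular_biaxial`}{`n` prolate and `m` biased towards `v`
#'     (`co_C > 0`).}
#'   \item{`molecular_d`}{`n` prolate and `m` biased towards `w`
#'     (`co_D < 0`).}
#' }
#' `concentration` controls the order strength (von Mises--Fisher kappa for
#' `n`; the same value biases `m` where applicable).
#'
#' @param kind Prototype name (see Description).
#' @param n Ensemble size.
#' @param concentration Positive order-strength parameter.
#' @param reference Single-row reference-tripod tibble the ensemble is built
#'   against (default axes: `w = z`, `v = x`, `u = y`).
#' @param seed RNG seed (applied locally).
#' @return A tripod-ensemble tibble; the reference is attached as attribute
#'   `"reference"`.
#' @export
synth_tripods <- function(kind = c("prolate", "phase_biaxial", "oblate",
                                   "prolate_free", "molecular_biaxial",
                                   "molecular_d"),
                          n = 1000L, concentration = 10,
                          reference = reference_tripods(w = c(0, 0, 1),
                                                        v = c(1, 0, 0)),
                          seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(concentration > 0, n >= 1L)
  rf <- reference_axes(reference)
  w <- rf$w[1, ]; v <- rf$v[1, ]; u <- rf$u[1, ]
  tri <- withr::with_seed(seed, {
    if (kind == "oblate") {
      psi <- stats::runif(n, 0, 2 * pi)
      tilt <- stats::rnorm(n, 0, 1 / sqrt(2 * concentration))
      nn <- outer(cos(psi), v) + outer(sin(psi), u) + outer(tilt, w)
      nn <- nn / sqrt(rowSums(nn^2))
    } else {
      ct <- rvmf_costheta(n, concentration)
      st <- sqrt(pmax(0, 1 - ct^2))
      psi <- if (kind == "phase_biaxial") {
        rbimodal_angle(n, concentration / 4, psi0 = pi / 2)  # bias towards u
      } else {
        stats::runif(n, 0, 2 * pi)
      }
      # frame: psi = 0 along v, psi = pi/2 along u
      nn <- outer(ct, w) + outer(st * cos(psi), v) + outer(st * sin(psi), u)
      nn <- nn / sqrt(rowSums(nn^2))
    }
    mm <- switch(kind,
      molecular_biaxial = biased_perpendicular(nn, v, concentration),
      molecular_d = biased_perpendicular(nn, w, concentration),
      random_perpendicular(nn))
    tripod_ensemble(n = nn, m = mm)
  })
  attr(tri, "reference") <- reference
  attr(tri, "kind") <- kind
  tri
}

# unit vectors perpendicular to rows of a, concentrated around the
# projection of target into each perpendicular plane (nematic bias)
biased_perpendicular <- function(a, target, concentration) {
  tproj <- matrix(target, nrow(a), 3, byrow = TRUE)
  tproj <- tproj - a * rowSums(a * tproj)
  nrm <- sqrt(rowSums(tproj^2))
  # fall back to a random perpendicular where target is parallel to a
  bad <- nrm < 1e-8
  if (any(bad)) {
    rp <- random_perpendicular(a[bad, , drop = FALSE])
    tproj[bad, ] <- rp
    nrm[bad] <- 1
  }
  e1 <- tproj / nrm
  e2 <- row_cross(a, e1)
  gamma <- rbimodal_angle(nrow(a), concentration / 2, psi0 = 0)
  e1 * cos(gamma) + e2 * sin(gamma)
}

#' Synthetic layered segment networks
#'
#' Segments confined near a stack of parallel planes normal to
#' `layer_normal`, mimicking the layered organization of a sinusoidal
#' network. With `in_plane_bias = 0` the in-plane directions are equally
#' spaced (planar-isotropic: the network tensor takes its closed-form layered
#' value and the preferred axis is degenerate); a positive bias concentrates
#' directions around `bias_direction` (modelling a preferred flow axis),
#' making the tensor biaxial.
#'
#' @param layer_normal Unit layer normal (the ground-truth plane axis `s2`).
#' @param n_layers Number of layers.
#' @param segments_per_layer Segments per layer.
#' @param in_plane_bias Concentration of in-plane directions around
#'   `bias_direction` (0 = isotropic in plane).
#' @param bias_direction In-plane preferred direction (ground-truth `s1`);
#'   default the first axis orthogonal to `layer_normal`.
#' @param spacing Layer spacing (micrometres).
#' @param extent Half-width of the layers (micrometres).
#' @param segment_length Segment length (micrometres).
#' @param tilt Out-of-plane direction jitter (radians, standard deviation).
#' @param seed RNG seed (applied locally).
#' @return A segment-set tibble; ground truth axes attached as attribute
#'   `"truth"` (list with `s2` and, when biased, `s1`).
#' @export
synth_layered_network <- function(layer_normal = c(0, 0, 1), n_layers = 5L,
                                  segments_per_layer = 200L,
                                  in_plane_bias = 0,
                                  bias_direction = NULL,
                                  spacing = 10, extent = 50,
                                  segment_length = 5, tilt = 0, seed = 1L) {
  layer_normal <- layer_normal / sqrt(sum(layer_normal^2))
  basis <- plane_basis(layer_normal)
  if (is.null(bias_direction)) bias_direction <- basis$e1
  b1 <- bias_direction - layer_normal * sum(bias_direction * layer_normal)
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- row_cross(matrix(layer_normal, 1), matrix(b1, 1))[1, ]
  n_seg <- n_layers * segments_per_layer
  withr::with_seed(seed, {
    layer <- rep(seq_len(n_layers) - (n_layers + 1) / 2, each = segments_per_layer)
    offs <- cbind(stats::runif(n_seg, -extent, extent),
                  stats::runif(n_seg, -extent, extent))
    mid <- outer(layer * spacing, layer_normal) +
      offs[, 1] %o% basis$e1 + offs[, 2] %o% basis$e2
    phi <- if (in_plane_bias > 0) {
      rbimodal_angle(n_seg, in_plane_bias, psi0 = 0)
    } else {
      rep(2 * pi * (seq_len(segments_per_layer) - 1L) / segments_per_layer,
          times = n_layers)
    }
    tl <- if (tilt > 0) stats::rnorm(n_seg, 0, tilt) else rep(0, n_seg)
    d <- outer(cos(phi) * cos(tl), b1) + outer(sin(phi) * cos(tl), b2) +
      outer(sin(tl), layer_normal)
    d <- d / sqrt(rowSums(d^2))
    seg <- tibble::tibble(
      mx = mid[, 1], my = mid[, 2], mz = mid[, 3],
      dx = d[, 1], dy = d[, 2], dz = d[, 3],
      length = rep(segment_length, n_seg))
    attr(seg, "truth") <- list(
      s2 = layer_normal,
      s1 = if (in_plane_bias > 0) b1 else NULL)
    seg
  })
}

plane_basis <- function(nrm) {
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - nrm * sum(ref * nrm)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- row_cross(matrix(nrm, 1), matrix(e1, 1))[1, ]
  list(e1 = e1, e2 = e2)
}

#' Synthetic toy lobule
#'
#' A complete end-to-end fixture: cells on a jittered lattice inside a
#' cylindrical shell (the central axis plays the vein direction), a layered
#' segment network whose layer normal is tangent to circles around the
#' central axis (so the director field is curved, as across a liver lobule),
#' and nematic polarity tripods sampled from the co-alignment model at a known
#' coupling `lambda_star` against the *measured* local network tensor at each
#' cell. Everything the analysis pipeline consumes is returned, with the
#' generator's ground truth alongside.
#'
#' @param seed RNG seed (applied locally).
#' @param lambda_star True coupling used to sample polarity.
#' @param r_inner,r_outer Shell radii (micrometres).
#' @param z_layers Number of cell layers along the axis.
#' @param lattice Cell lattice spacing (micrometres).
#' @param segments_per_cell Network segments generated around each cell.
#' @param in_plane_bias Concentration of segment directions around the local
#'   radial axis (makes the local tensor biaxial).
#' @param tilt Out-of-plane segment jitter (radians).
#' @param radius Region-of-interest radius used to measure the local network
#'   tensor (micrometres).
#' @param alpha2,alpha1 Model eigenvalue weights (see [model_config()]).
#' @return A list of class `toy_lobule`: `cells` (tibble: `id`, positions,
#'   tripod columns `nx..lz`, polarity-tensor columns `xx..zz`), `segments`,
#'   `field` (the measured [network_field()] at the cells), `truth` (list:
#'   `lambda_star`, per-cell ground-truth frame columns, parameters).
#' @export
synth_toy_lobule <- function(seed = 1L, lambda_star = 2,
                             r_inner = 25, r_outer = 65, z_layers = 8L,
                             lattice = 7, segments_per_cell = 20L,
                             in_plane_bias = 1, tilt = 0.15, radius = 20,
                             alpha2 = -0.19, alpha1 = 0.38) {
  withr::with_seed(seed, {
    xs <- seq(-r_outer, r_outer, by = lattice)
    gridpts <- expand.grid(x = xs, y = xs,
                           z = lattice * (seq_len(z_layers) - (z_layers + 1) / 2))
    gridpts <- gridpts + matrix(stats::runif(3L * nrow(gridpts), -0.2, 0.2) * lattice,
                                ncol = 3L)
    r <- sqrt(gridpts$x^2 + gridpts$y^2)
    cells <- tibble::as_tibble(gridpts[r >= r_inner & r <= r_outer, ])
    n_cells <- nrow(cells)
    cells$id <- seq_len(n_cells)

    # local frame: s1 radial, s2 tangential (curved layer normal), s3 = z
    phi <- atan2(cells$y, cells$x)
    s1 <- cbind(cos(phi), sin(phi), 0)
    s2 <- cbind(-sin(phi), cos(phi), 0)
    s3 <- matrix(rep(c(0, 0, 1), each = n_cells), ncol = 3L)

    # network: layered segments around each cell, in the (s1, s3) plane
    k <- segments_per_cell
    off <- matrix(stats::rnorm(3L * n_cells * k), ncol = 3L)
    off <- off / sqrt(rowSums(off^2)) *
      (0.9 * radius) * stats::runif(n_cells * k)^(1 / 3)
    idx <- rep(seq_len(n_cells), each = k)
    mids <- cbind(cells$x[idx], cells$y[idx], cells$z[idx]) + off
    psi <- rbimodal_angle(n_cells * k, in_plane_bias, psi0 = 0)
    tl <- stats::rnorm(n_cells * k, 0, tilt)
    d <- s1[idx, ] * (cos(psi) * cos(tl)) + s3[idx, ] * (sin(psi) * cos(tl)) +
      s2[idx, ] * sin(tl)
    d <- d / sqrt(rowSums(d^2))
    segments <- tibble::tibble(
      mx = mids[, 1], my = mids[, 2], mz = mids[, 3],
      dx = d[, 1], dy = d[, 2], dz = d[, 3],
      length = rep(4, n_cells * k))

    # measure the local network tensor, then sample polarity against it
    field <- network_field(segments, cells, radius = radius)
    nn <- matrix(NA_real_, n_cells, 3L)
    for (i in seq_len(n_cells)) {
      Si <- matrix(c(field$xx[i], field$xy[i], field$xz[i],
                     field$xy[i], field$yy[i], field$yz[i],
                     field$xz[i], field$yz[i], field$zz[i]), 3, 3)
      nn[i, ] <- sample_axis_boltzmann(1L, lambda_star * alpha2, Si)
    }
    mm <- random_perpendicular(nn)
    tri <- tripod_ensemble(n = nn, m = mm)

    # polarity tensors with the mean eigenvalue weights (n = a2, m = a1)
    alpha3 <- -alpha1 - alpha2
    ax <- tripod_axes(tri)
    mats <- lapply(seq_len(n_cells), function(i) {
      alpha1 * tcrossprod(ax$m[i, ]) + alpha2 * tcrossprod(ax$n[i, ]) +
        alpha3 * tcrossprod(ax$l[i, ])
    })
    cells <- dplyr::bind_cols(cells[, c("id", "x", "y", "z")], tri,
                              tensor_cols(mats))
    structure(list(
      cells = cells, segments = segments, field = field,
      truth = list(lambda_star = lambda_star,
                   s1 = s1, s2 = s2, s3 = s3,
                   in_plane_bias = in_plane_bias, tilt = tilt,
                   alpha2 = alpha2, alpha1 = alpha1)
    ), class = "toy_lobule")
  })
}

#' @export
print.toy_lobule <- function(x, ...) {
  cat("<toy_lobule>", nrow(x$cells), "cells,", nrow(x$segments),
      "segments, lambda* =", x$truth$lambda_star, "\n")
  invisible(x)
}
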
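#' Icosphere meshes
#'
#' Geodesic sphere obtained by subdividing an icosahedron `subdiv` times and
#' normalizing vertices to the given radius. Used as the probe-direction set of
#' the star-convexity check and as a convenient synthetic mesh.
#'
#' @param subdiv Number of 4-to-1 subdivisions (0 gives the icosahedron;
#'   3 gives 642 vertices).
#' @param radius Sphere radius.
#' @param center Sphere center (length-3).
#' @return A list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
icosphere_mesh <- function(subdiv = 3L, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      idx <- nv + length(newv)
      mid_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4 * k - 3, ] <- c(a, ab, ca)
      newf[4 * k - 2, ] <- c(b, bc, ab)
      newf[4 * k - 1, ] <- c(c, ca, bc)
      newf[4 * k, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  list(vertices = sweep(v * radius, 2, center, `+`), faces = f)
}

# unsigned solid angle subtended at the origin by triangles (Van Oosterom &
# Strackee 1983); p1, p2, p3 are n x 3 matrices of vertex positions relative
# to the viewpoint.
triangle_solid_angle <- function(p1, p2, p3) {
  r1 <- sqrt(rowSums(p1^2)); r2 <- sqrt(rowSums(p2^2)); r3 <- sqrt(rowSums(p3^2))
  triple <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  denom <- r1 * r2 * r3 + rowSums(p1 * p2) * r3 +
    rowSums(p1 * p3) * r2 + rowSums(p2 * p3) * r1
  2 * atan2(abs(triple), denom)
}

#' Radially project a labelled surface onto the unit sphere
#'
#' Each face contributes one pattern sample: the unit radial direction of its
#' centroid (seen from the projection center), the exact solid angle the face
#' subtends at the center (spherical-triangle formula) as quadrature weight,
#' and the face marker density as value. Because weights are solid angles, a
#' uniform marker on a surface of *any* star-convex shape projects to a
#' uniform pattern: anisotropy of cell shape does not leak into the pattern.
#'
#' @param surface A [labeled_surface()].
#' @param check_star_convex Verify star-convexity by casting 642 probe rays
#'   from the center and requiring a single surface hit per ray.
#' @param binarize Optional threshold: face values are replaced by
#'   `value >= binarize` (0/1 apical indicator).
#' @return A surface-pattern tibble (see [surface_pattern()]).
#' @export
project_to_sphere <- function(surface, check_star_convex = TRUE,
                              binarize = NULL) {
  stopifnot(inherits(surface, "labeled_surface"))
  g <- face_geometry(surface)
  keep <- g$area > 1e-12 * max(g$area)
  if (any(!keep)) {
    message("skipping ", sum(!keep), " zero-area faces")
  }
  ctr <- surface$center
  p1 <- sweep(g$p1[keep, , drop = FALSE], 2, ctr)
  p2 <- sweep(g$p2[keep, , drop = FALSE], 2, ctr)
  p3 <- sweep(g$p3[keep, , drop = FALSE], 2, ctr)
  cen <- sweep(g$centroid[keep, , drop = FALSE], 2, ctr)
  rad <- sqrt(rowSums(cen^2))
  if (any(rad <= 0)) stop("face centroid at the projection center", call. = FALSE)
  if (check_star_convex) {
    bad <- star_convexity_violations(p1, p2, p3)
    if (nrow(bad) > 0L) {
      stop("surface is not star-convex about the center; ", nrow(bad),
           " probe directions hit multiple faces, e.g. (",
           paste(signif(bad[1, ], 3), collapse = ", "), ")", call. = FALSE)
    }
  }
  omega <- triangle_solid_angle(p1, p2, p3)
  vals <- surface$face_values[keep]
  if (!is.null(binarize)) vals <- as.numeric(vals >= binarize)
  total <- sum(omega)
  if (abs(total - 4 * pi) > 0.01 * 4 * pi) {
    warning("projected solid angles sum to ", signif(total, 6),
            " (expected 4*pi); surface may not be closed", call. = FALSE)
  }
  surface_pattern(cen[, 1] / rad, cen[, 2] / rad, cen[, 3] / rad,
                  weight = omega, value = vals)
}

# probe 642 quasi-uniform directions; return directions hitting > 1 face
star_convexity_violations <- function(p1, p2, p3) {
  probes <- icosphere_mesh(3L)$vertices
  e1 <- p2 - p1
  e2 <- p3 - p1
  hits <- integer(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    d <- probes[i, ]
    pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                d[3] * e2[, 1] - d[1] * e2[, 3],
                d[1] * e2[, 2] - d[2] * e2[, 1])
    det <- rowSums(e1 * pv)
    ok <- abs(det) > 1e-12
    tv <- -p1
    u <- rowSums(tv * pv) / det
    qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
                tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
                tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
    vpar <- (qv[, 1] * d[1] + qv[, 2] * d[2] + qv[, 3] * d[3]) / det
    tt <- rowSums(e2 * qv) / det
    # interior hits only: boundary tolerance avoids double-counting shared edges
    eps <- 1e-9
    hits[i] <- sum(ok & u > eps & vpar > eps & (u + vpar) < 1 - eps & tt > eps)
  }
  probes[hits > 1L, , drop = FALSE]
}
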
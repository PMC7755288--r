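#' Co-orientational order parameters (COOP)
#'
#' Averaged direction cosines between per-object principal axes
#' (`n`, `m`, `l`) and per-object reference axes (`w`, `v`, `u`):
#' \deqn{co\text{-}S = \tfrac12\langle 3 (n \cdot w)^2 - 1\rangle,\quad
#'       co\text{-}P = \tfrac32\langle (n \cdot u)^2 - (n \cdot v)^2\rangle,}
#' \deqn{co\text{-}D = \tfrac32\langle (l \cdot w)^2 - (m \cdot w)^2\rangle,\quad
#'       co\text{-}C = \tfrac12\langle (l \cdot u)^2 - (l \cdot v)^2
#'                     + (m \cdot v)^2 - (m \cdot u)^2\rangle.}
#' Unlike the classical order parameters ([oop()]), the axis ordering is
#' prescribed per object by the reference tensors, so COOP vary continuously
#' when system parameters vary smoothly. Bounds: `co_S` in `[-1/2, 1]`,
#' `|co_P| <= 3/2`, `|co_D| <= 3/2`, `|co_C| <= 1`.
#'
#' @param tripods Tripod-ensemble tibble (see [tripod_ensemble()]).
#' @param references Reference-tripod tibble (see [reference_tripods()]);
#'   either one row per tripod or a single row recycled to all.
#' @param n_boot Bootstrap resamples for the standard errors.
#' @param seed Seed for the bootstrap resampling (applied locally; the global
#'   RNG state is untouched).
#' @return A `coop_result`: list with `estimates` (tibble `parameter`,
#'   `value`, `se`), `n`, and `dropped` (rows excluded by the caller, if any).
#' @export
coop <- function(tripods, references, n_boot = 1000L, seed = 1L) {
  validate_tripods(tripods)
  if (nrow(references) == 1L && nrow(tripods) > 1L) {
    references <- references[rep(1L, nrow(tripods)), ]
  }
  if (nrow(references) != nrow(tripods)) {
    stop("tripods and references must pair one-to-one", call. = FALSE)
  }
  terms <- coop_terms(tripods, references)
  est <- colMeans(terms)
  se <- boot_se(terms, n_boot = n_boot, seed = seed)
  new_coop_result(est, se, n = nrow(terms))
}

# per-sample contributions to the four COOP (n x 4 matrix)
coop_terms <- function(tripods, references) {
  ax <- tripod_axes(tripods)
  rf <- reference_axes(references)
  nw <- rowSums(ax$n * rf$w)^2
  nv <- rowSums(ax$n * rf$v)^2
  nu <- rowSums(ax$n * rf$u)^2
  mw <- rowSums(ax$m * rf$w)^2
  mv <- rowSums(ax$m * rf$v)^2
  mu <- rowSums(ax$m * rf$u)^2
  lw <- rowSums(ax$l * rf$w)^2
  lv <- rowSums(ax$l * rf$v)^2
  lu <- rowSums(ax$l * rf$u)^2
  cbind(co_S = 0.5 * (3 * nw - 1),
        co_P = 1.5 * (nu - nv),
        co_D = 1.5 * (lw - mw),
        co_C = 0.5 * (lu - lv + mv - mu))
}

boot_se <- function(terms, n_boot, seed) {
  n <- nrow(terms)
  if (n < 2L || n_boot < 2L) return(rep(NA_real_, ncol(terms)))
  withr::with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      colMeans(terms[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(ncol(terms)))
  })
  apply(reps, 1L, stats::sd)
}

new_coop_result <- function(est, se, n, dropped = 0L) {
  structure(list(
    estimates = tibble::tibble(
      parameter = c("co_S", "co_P", "co_D", "co_C"),
      value = as.numeric(est), se = as.numeric(se)),
    n = n, dropped = dropped
  ), class = "coop_result")
}

#' @export
print.coop_result <- function(x, ...) {
  cat("<coop_result> n =", x$n,
      if (x$dropped > 0L) paste0("(", x$dropped, " dropped)"), "\n")
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.coop_result <- function(x, ...) x$estimates

#' @export
glance.coop_result <- function(x, ...) {
  out <- tibble::as_tibble(as.list(stats::setNames(x$estimates$value,
                                                   x$estimates$parameter)))
  out$n <- x$n
  out
}

#' COOP against a set of reference nematic tensors
#'
#' Builds one reference tripod per object from the eigen-system of its
#' reference tensor (ordering `eps1 >= eps3 >= eps2`; `w` is the
#' smallest-eigenvalue axis, `v` the largest, `u` the middle one) and
#' evaluates [coop()]. Degenerate reference tensors (eigenvalue gap below
#' `degeneracy_tol` relative to scale) are flagged and their rows excluded.
#'
#' This is the pipeline used to compare cell-polarity tripods with the local
#' anisotropy of a transport network (`w = s2` plane axis, `v = s1` preferred
#' axis, `u = s3`).
#'
#' @inheritParams coop
#' @param ref_tensors Tibble with tensor component columns
#'   `xx, xy, xz, yy, yz, zz` (one row per tripod), or a list of 3x3 matrices.
#' @param degeneracy_tol Relative eigenvalue-gap tolerance below which a
#'   reference tensor is treated as degenerate.
#' @return A `coop_result`; `dropped` counts excluded rows.
#' @export
coop_vs_tensors <- function(tripods, ref_tensors, degeneracy_tol = 1e-6,
                            n_boot = 1000L, seed = 1L) {
  validate_tripods(tripods)
  refs <- reference_frames_from_tensors(ref_tensors, degeneracy_tol)
  if (nrow(refs) == 1L && nrow(tripods) > 1L) {
    refs <- refs[rep(1L, nrow(tripods)), ]
  }
  if (nrow(refs) != nrow(tripods)) {
    stop("tripods and reference tensors must pair one-to-one", call. = FALSE)
  }
  keep <- !refs$degenerate
  if (any(!keep)) {
    message("excluding ", sum(!keep), " objects with degenerate reference tensors")
  }
  if (!any(keep)) stop("all reference tensors degenerate", call. = FALSE)
  res <- coop(tripods[keep, ], refs[keep, ], n_boot = n_boot, seed = seed)
  res$dropped <- sum(!keep)
  res
}

#' Reference tripods from nematic tensors
#'
#' Eigen-orders each tensor (`eps1 >= eps3 >= eps2`) and returns the reference
#' tripod `w = e2`, `v = e1`, `u = e3` with a degeneracy flag.
#'
#' @inheritParams coop_vs_tensors
#' @return A reference-tripod tibble with an added `degenerate` column.
#' @export
reference_frames_from_tensors <- function(ref_tensors, degeneracy_tol = 1e-6) {
  mats <- tensor_list(ref_tensors)
  rows <- lapply(mats, function(m) {
    ax <- ordered_axes(m, tol = degeneracy_tol)
    c(w = ax$a2, v = ax$a1, u = ax$a3, deg = as.numeric(ax$degenerate))
  })
  tab <- do.call(rbind, rows)
  out <- reference_tripods(w = tab[, 1:3, drop = FALSE],
                           v = tab[, 4:6, drop = FALSE],
                           u = tab[, 7:9, drop = FALSE])
  out$degenerate <- tab[, 10] > 0
  out
}

# accept list of matrices or a tibble of component columns
tensor_list <- function(ref_tensors) {
  if (is.list(ref_tensors) && !is.data.frame(ref_tensors)) {
    return(lapply(ref_tensors, function(m) unclass(as_nematic_tensor(m))))
  }
  need <- c("xx", "xy", "xz", "yy", "yz", "zz")
  miss <- setdiff(need, names(ref_tensors))
  if (length(miss) > 0L) {
    stop("tensor table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(ref_tensors)), function(i) {
    r <- ref_tensors[i, ]
    matrix(c(r$xx, r$xy, r$xz, r$xy, r$yy, r$yz, r$xz, r$yz, r$zz), 3, 3)
  })
}

tensor_cols <- function(mats) {
  tab <- t(vapply(mats, function(m) {
    c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
  }, numeric(6)))
  tibble::tibble(xx = tab[, 1], xy = tab[, 2], xz = tab[, 3],
                 yy = tab[, 4], yz = tab[, 5], zz = tab[, 6])
}

#' Classical biaxial orientational order parameters (OOP)
#'
#' The Zannoni-convention order parameters `S`, `P`, `D`, `C` of a tripod
#' ensemble. The reference frame is taken from the ensemble itself: for every
#' relabelling `pi` of the principal axes, the averaged tensor `<Q>` is
#' diagonalized and its eigenvectors assigned to the reference axes in every
#' order `rho`; the pair maximizing `|S|` with `P >= 0` and `C >= 0` (ties
#' broken lexicographically) is selected. Because the frame is inferred from
#' the ensemble, OOP can jump discontinuously along smooth parameter paths
#' when the selected permutation switches — the motivation for [coop()].
#'
#' @inheritParams coop
#' @param commutator_tol Relative tolerance on the commutator of `<Q>` and
#'   `<B>` above which the ensemble is flagged as not co-diagonalizable.
#' @return An `oop_result`: list with `estimates` (tibble), the selected
#'   permutations `pi_perm` and `rho_perm`, `co_diagonalizable` flag, `n`.
#' @export
oop <- function(tripods, n_boot = 1000L, seed = 1L, commutator_tol = 0.05) {
  validate_tripods(tripods)
  if (nrow(tripods) < 2L) stop("need an ensemble of at least 2 tripods", call. = FALSE)
  ax <- tripod_axes(tripods)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  axes_list <- list(ax$n, ax$m, ax$l)

  best <- NULL
  for (pi_i in seq_along(perms)) {
    p <- perms[[pi_i]]
    tri <- tripod_ensemble(axes_list[[p[1]]], axes_list[[p[2]]], axes_list[[p[3]]])
    qb <- mean_qb(tri)
    ev <- joint_eigenframe(qb$Q, qb$B)
    for (rho_i in seq_along(perms)) {
      r <- perms[[rho_i]]
      refs <- reference_tripods(w = matrix(ev[, r[1]], 1), v = matrix(ev[, r[2]], 1),
                                u = matrix(ev[, r[3]], 1))
      vals <- colMeans(coop_terms(tri, refs[rep(1L, nrow(tri)), ]))
      cand <- list(S = vals[1], P = vals[2], D = vals[3], C = vals[4],
                   pi_i = pi_i, rho_i = rho_i, tri = tri, refs = refs, qb = qb)
      if (is.null(best) || better_oop(cand, best)) best <- cand
    }
  }
  comm <- best$qb$Q %*% best$qb$B - best$qb$B %*% best$qb$Q
  nq <- norm(best$qb$Q, "F"); nb <- norm(best$qb$B, "F")
  co_diag <- !(nq > 0.05 && nb > 0.05 &&
                 norm(comm, "F") > commutator_tol * nq * nb)
  terms <- coop_terms(best$tri, best$refs[rep(1L, nrow(best$tri)), ])
  se <- boot_se(terms, n_boot = n_boot, seed = seed)
  structure(list(
    estimates = tibble::tibble(parameter = c("S", "P", "D", "C"),
                               value = unname(c(best$S, best$P, best$D, best$C)),
                               se = as.numeric(se)),
    pi_perm = perms[[best$pi_i]], rho_perm = perms[[best$rho_i]],
    co_diagonalizable = co_diag, n = nrow(tripods)
  ), class = "oop_result")
}

# Common eigenframe of <Q> and <B>: eigenvectors of <Q>, refined inside
# (near-)degenerate eigenvalue clusters of <Q> by diagonalizing the
# restriction of <B> there. For perfectly uniaxial ensembles this recovers
# the biaxial frame that <Q> alone leaves undetermined.
joint_eigenframe <- function(Q, B, tol = 1e-7) {
  es <- eigen(Q, symmetric = TRUE)
  vals <- es$values
  V <- es$vectors
  scale <- max(abs(vals), 1e-12)
  cl <- cumsum(c(1, diff(vals) < -tol * scale))  # cluster id per eigenvalue
  for (g in unique(cl)) {
    idx <- which(cl == g)
    if (length(idx) > 1L) {
      Vc <- V[, idx, drop = FALSE]
      eb <- eigen(crossprod(Vc, B %*% Vc), symmetric = TRUE)
      V[, idx] <- Vc %*% eb$vectors
    }
  }
  V
}

# Zannoni selection order: max |S|, then P >= 0, then C >= 0, then
# lexicographic (pi, rho). Tolerance guards make the choice deterministic
# under exact degeneracy.
better_oop <- function(cand, best, tol = 1e-9) {
  key <- function(x) c(abs(x$S), x$P >= -tol, x$C >= -tol, -x$pi_i, -x$rho_i)
  a <- key(cand); b <- key(best)
  for (i in seq_along(a)) {
    if (a[i] > b[i] + (if (i == 1) tol else 0)) return(TRUE)
    if (a[i] < b[i] - (if (i == 1) tol else 0)) return(FALSE)
  }
  FALSE
}

#' @export
print.oop_result <- function(x, ...) {
  cat("<oop_result> n =", x$n,
      " pi = (", paste(x$pi_perm, collapse = " "), ")",
      " rho = (", paste(x$rho_perm, collapse = " "), ")",
      if (!x$co_diagonalizable) " [warning: <Q>, <B> not co-diagonalizable]",
      "\n")
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.oop_result <- function(x, ...) x$estimates

#' @export
glance.oop_result <- function(x, ...) {
  out <- tibble::as_tibble(as.list(stats::setNames(x$estimates$value,
                                                   x$estimates$parameter)))
  out$n <- x$n
  out$co_diagonalizable <- x$co_diagonalizable
  out
}
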
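# shared fixtures, built in code

li <- function(l, m) l * (l + 1L) + m + 1L

rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# random real band-limited pattern on a Gauss grid; returns pattern + coefs
make_bandlimited <- function(lmax, grid = sphere_grid_gauss(lmax), seed = 1) {
  withr::with_seed(seed, {
    nc <- (lmax + 1L)^2
    coef <- complex(real = stats::rnorm(nc), imaginary = stats::rnorm(nc))
    for (l in 0:lmax) for (m in 0:l) {
      i <- li(l, m); j <- li(l, -m)
      if (m == 0) coef[i] <- complex(real = Re(coef[i]))
      else coef[j] <- (-1)^m * Conj(coef[i])
    }
    d <- structure(list(lmax = as.integer(lmax), coef = coef,
                        convention = "orthonormal_condon_shortley"),
                   class = "sph_decomp")
    vals <- sph_reconstruct(d, grid)
    list(pattern = surface_pattern(grid$x, grid$y, grid$z, grid$weight, vals),
         coef = coef, grid = grid)
  })
}

# sample unit vectors from a von Mises-Fisher distribution around mu
rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  u <- stats::runif(n)
  ct <- 1 + log1p(-u * (1 - exp(-2 * kappa))) / kappa
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- stats::runif(n, 0, 2 * pi)
  # frame around mu
  ref <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - mu * sum(ref * mu); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2], mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  outer(ct, mu) + outer(st * cos(phi), e1) + outer(st * sin(phi), e2)
}

# cached toy lobule shared across test files
toy_lobule_cache <- new.env()
get_toy_lobule <- function(seed = 1L, lambda_star = 2) {
  key <- paste0("lob_", seed, "_", lambda_star)
  if (is.null(toy_lobule_cache[[key]])) {
    toy_lobule_cache[[key]] <- synth_toy_lobule(seed = seed,
                                                lambda_star = lambda_star)
  }
  toy_lobule_cache[[key]]
}

tripod_cols <- c("nx", "ny", "nz", "mx", "my", "mz", "lx", "ly", "lz")
tensor_comp_cols <- c("xx", "xy", "xz", "yy", "yz", "zz")

# mixture-path family for the continuity diagnostic: pool A clustered along
# z, pool B along x, deterministic composition in t with common samples
make_mixture_family <- function(n_pool = 1500L, kappa = 20, seed = 7L) {
  withr::with_seed(seed, {
    poolA_n <- rvmf(n_pool, c(0, 0, 1), kappa)
    poolB_n <- rvmf(n_pool, c(1, 0, 0), kappa)
    poolA_m <- nematiq:::random_perpendicular(poolA_n)
    poolB_m <- nematiq:::random_perpendicular(poolB_n)
  })
  refs <- reference_tripods(w = c(0, 0, 1), v = c(1, 0, 0))
  function(t) {
    k <- round(t * n_pool)
    n <- rbind(poolA_n[seq_len(k), , drop = FALSE],
               poolB_n[seq_len(n_pool - k), , drop = FALSE])
    m <- rbind(poolA_m[seq_len(k), , drop = FALSE],
               poolB_m[seq_len(n_pool - k), , drop = FALSE])
    list(tripods = tripod_ensemble(n, m), references = refs)
  }
}
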
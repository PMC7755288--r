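test_that("variant energies reduce to eigenvalue contractions", {
  S <- diag(c(0.4, -0.3, -0.1))
  cfg <- model_config(lambda = 2)
  # a2 along an eigenvector: the contraction equals that eigenvalue
  H <- variant_energy(n = c(1, 0, 0), m = c(0, 1, 0), l = c(0, 0, 1), S, cfg)
  expect_equal(H, -2 * (-0.19) * 0.4, tolerance = 1e-12)
  # a2 along a zero-eigenvalue direction: contraction term vanishes
  S0 <- diag(c(0.5, -0.5, 0))
  H0 <- variant_energy(n = c(0, 0, 1), m = c(1, 0, 0), l = c(0, 1, 0), S0, cfg)
  expect_equal(H0, 0, tolerance = 1e-12)
  # full tensor = eigenvalue-weighted sum of axis-wise contractions
  cfg_full <- model_config(lambda = 2, variant = "full_tensor")
  tri <- list(n = c(0, 0, 1), m = c(1, 0, 0), l = c(0, 1, 0))
  Hfull <- variant_energy(tri$n, tri$m, tri$l, S, cfg_full)
  parts <- -2 * (cfg_full$alpha1 * S[1, 1] + cfg_full$alpha2 * S[3, 3] +
                   (-cfg_full$alpha1 - cfg_full$alpha2) * S[2, 2])
  expect_equal(Hfull, parts, tolerance = 1e-12)
})

test_that("zero coupling gives an isotropic ensemble with vanishing COOP", {
  s <- sample_boltzmann(model_config(lambda = 0, n_samples = 10000, seed = 41))
  res <- coop(s$tripods, s$reference_frame[, 1:9], n_boot = 200, seed = 41)
  expect_lt(max(abs(res$estimates$value) / (3 * res$estimates$se)), 1)
  expect_equal(s$energies, rep(0, 10000))
})

test_that("strong coupling aligns the ring axis with the plane axis s2", {
  s <- sample_boltzmann(model_config(lambda = 1000, n_samples = 2000, seed = 42))
  res <- coop(s$tripods, s$reference_frame[, 1:9], n_boot = 0)
  expect_gt(res$estimates$value[1], 0.9)
  # a2 concentrates on the smallest-eigenvalue axis of S (alpha2 < 0)
  w <- as.numeric(as.matrix(s$reference_frame[1, c("wx", "wy", "wz")]))
  align <- abs(cbind(s$tripods$nx, s$tripods$ny, s$tripods$nz) %*% w)
  expect_gt(mean(align), 0.97)
})

test_that("flipping the sign of alpha2 attracts the axis to the largest eigenvalue", {
  cfg <- model_config(lambda = 1000, alpha2 = +0.19, n_samples = 2000,
                      seed = 43)
  s <- sample_boltzmann(cfg)
  v <- as.numeric(as.matrix(s$reference_frame[1, c("vx", "vy", "vz")]))  # v = e1
  align <- abs(cbind(s$tripods$nx, s$tripods$ny, s$tripods$nz) %*% v)
  expect_gt(mean(align), 0.97)
})

test_that("sampled moments match direct quadrature of the Boltzmann density", {
  cfg <- model_config(lambda = 2, n_samples = 10000, seed = 44)
  S <- unclass(default_reference_tensor())
  s <- sample_boltzmann(cfg, S)
  g <- sphere_grid_gauss(64)
  dirs <- as.matrix(g[, c("x", "y", "z")])
  q <- rowSums((dirs %*% S) * dirs)
  wts <- g$weight * exp(cfg$lambda * cfg$alpha2 * q)
  wts <- wts / sum(wts)
  mq_quad <- sum(wts * q)
  ax <- cbind(s$tripods$nx, s$tripods$ny, s$tripods$nz)
  q_emp <- rowSums((ax %*% S) * ax)
  se <- stats::sd(q_emp) / sqrt(length(q_emp))
  expect_lt(abs(mean(q_emp) - mq_quad), 3 * se)
})

test_that("the COOP sweep is monotone in co_S with coincident co_C and co_D", {
  sw <- coop_sweep(c(0, 0.5, 1, 2, 4, 8),
                   config = model_config(n_samples = 10000, seed = 45),
                   n_boot = 100)
  # common random numbers across the grid make the curve strictly increasing
  expect_true(all(diff(sw$co_S) > 0))
  expect_true(all(sw$co_P[-1] > -3 * sw$se_co_P[-1]))
  # uniaxial objects: the model predicts co_C identical to co_D
  expect_lt(max(abs(sw$co_C - sw$co_D)), 0.05)
})

test_that("a uniaxial reference (degenerate upper pair) suppresses phase biaxiality", {
  S <- diag(c(0.2, 0.2, -0.4))  # axially symmetric around z = smallest axis
  s <- sample_boltzmann(model_config(lambda = 4, n_samples = 10000, seed = 46), S)
  refs <- reference_tripods(w = c(0, 0, 1), v = c(1, 0, 0))
  res <- coop(s$tripods, refs, n_boot = 200, seed = 46)
  expect_gt(res$estimates$value[1], 0)  # ordered towards w
  expect_lt(abs(res$estimates$value[2]), 3 * res$estimates$se[2])  # co_P ~ 0
})

test_that("coupling strength is recovered by inverting the sweep (fixed seeds)", {
  for (lam_star in c(0.5, 2, 4)) {
    cfg <- model_config(lambda = lam_star, n_samples = 10000, seed = 47)
    s <- sample_boltzmann(cfg)
    obs <- coop(s$tripods, s$reference_frame[, 1:9], n_boot = 100, seed = 47)
    fit <- fit_lambda(obs, config = model_config(n_samples = 10000, seed = 47))
    expect_lt(abs(fit$lambda_hat - lam_star) / lam_star, 0.1)
    expect_true(fit$interval[1] <= lam_star && lam_star <= fit$interval[2])
  }
})

test_that("degenerate observed values hit the fit boundaries", {
  obs0 <- tibble::tibble(parameter = c("co_S", "co_P", "co_D", "co_C"),
                         value = c(0, 0, 0, 0), se = rep(0.01, 4))
  fit0 <- fit_lambda(obs0, config = model_config(n_samples = 4000, seed = 48),
                     lambdas = seq(0, 4, 0.5))
  expect_lt(fit0$lambda_hat, 0.3)

  obs1 <- tibble::tibble(parameter = c("co_S", "co_P", "co_D", "co_C"),
                         value = c(1, 0, 0, 0), se = rep(0.01, 4))
  expect_warning(
    fit1 <- fit_lambda(obs1, config = model_config(n_samples = 4000, seed = 48),
                       lambdas = seq(0, 4, 0.5)),
    "maximum")
  expect_equal(fit1$lambda_hat, 4)
  expect_true(fit1$boundary)

  obs_bad <- tibble::tibble(parameter = c("co_S", "co_P", "co_D", "co_C"),
                            value = c(-0.4, 0, 0, 0), se = rep(0.001, 4))
  expect_error(fit_lambda(obs_bad,
                          config = model_config(n_samples = 4000, seed = 48),
                          lambdas = seq(0, 4, 0.5)),
               "outside model range")
})

test_that("sampling is reproducible under a fixed seed and leaves the global RNG alone", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  s1 <- sample_boltzmann(model_config(lambda = 1, n_samples = 100, seed = 49))
  after <- stats::runif(1)
  expect_equal(before, after)  # with_seed restored the RNG state
  s2 <- sample_boltzmann(model_config(lambda = 1, n_samples = 100, seed = 49))
  expect_identical(s1$tripods, s2$tripods)
})
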
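test_that("synthetic patterns reproduce the vectorial/nematic classification", {
  cap <- sph_power_spectrum(sph_decompose(synth_pattern("cap"), 6))
  aniso <- cap$power[-1]
  expect_equal(which.max(aniso), 1L)  # l = 1 peak: vectorial

  for (kind in c("ring", "bipolar")) {
    ps <- sph_power_spectrum(sph_decompose(synth_pattern(kind), 6))
    expect_lt(max(ps$power[ps$l %% 2 == 1]), 1e-10)
    expect_equal(which.max(ps$power[-1]), 2L)  # l = 2 peak: nematic
  }

  # total mass is normalized to one
  expect_equal(pattern_mass(synth_pattern("mixture")), 1, tolerance = 1e-12)
  expect_equal(pattern_mass(synth_pattern("ring", concentration = Inf)), 1)
})

test_that("tripod prototypes reproduce the labelled sign patterns", {
  refs <- reference_tripods(w = c(0, 0, 1), v = c(1, 0, 0))
  val <- function(kind, conc = 10) {
    tri <- synth_tripods(kind, n = 4000, concentration = conc, seed = 51)
    coop(tri, refs, n_boot = 0)$estimates$value
  }
  prolate <- val("prolate", conc = 60)
  expect_gt(prolate[1], 0.9)
  expect_lt(max(abs(prolate[2:4])), 0.1)

  oblate <- val("oblate")
  expect_lt(oblate[1], 0)

  pb <- val("phase_biaxial")
  expect_gt(pb[1], 0)
  expect_gt(pb[2], 0.1)

  mb <- val("molecular_biaxial")
  expect_gt(mb[1], 0)
  expect_gt(mb[4], 0.1)

  md <- val("molecular_d")
  expect_gt(md[1], 0)
  expect_lt(md[3], -0.1)

  # deterministic under seed
  t1 <- synth_tripods("prolate", n = 50, seed = 52)
  t2 <- synth_tripods("prolate", n = 50, seed = 52)
  expect_identical(t1$nx, t2$nx)
})

test_that("layered networks carry recoverable ground truth", {
  # strong layering, no in-plane bias: s2 = layer normal, s1 degenerate
  net <- synth_layered_network(layer_normal = c(0, 1, 0), seed = 53)
  res <- network_tensor(net, center = c(0, 0, 0), radius = 100)
  expect_equal(abs(res$s2), c(0, 1, 0), tolerance = 1e-9)
  expect_true(res$degenerate)

  # in-plane bias on: s1 = bias direction, s2 = layer normal, biaxial
  net2 <- synth_layered_network(layer_normal = c(0, 0, 1), in_plane_bias = 2,
                                tilt = 0.1, seed = 54)
  res2 <- network_tensor(net2, center = c(0, 0, 0), radius = 100)
  truth <- attr(net2, "truth")
  expect_gt(abs(sum(res2$s2 * truth$s2)), 0.99)
  expect_gt(abs(sum(res2$s1 * truth$s1)), 0.99)
  expect_false(res2$degenerate)

  # layered field: plane axis recovered at > 90% of probed centers
  centers <- tibble::tibble(x = stats::runif(20, -30, 30),
                            y = stats::runif(20, -30, 30), z = 0)
  field <- network_field(net2, centers, radius = 15)
  ok <- !field$empty
  align <- abs(field$s2x[ok] * truth$s2[1] + field$s2y[ok] * truth$s2[2] +
                 field$s2z[ok] * truth$s2[3])
  expect_gt(mean(align > 0.95), 0.9)
})

test_that("the toy lobule closes the loop at zero coupling", {
  lob0 <- synth_toy_lobule(seed = 55, lambda_star = 0, z_layers = 4L,
                           lattice = 10)
  keep <- !lob0$field$empty & !lob0$field$degenerate
  res <- coop_vs_tensors(lob0$cells[keep, tripod_cols],
                         lob0$field[keep, tensor_comp_cols],
                         n_boot = 200, seed = 55)
  expect_lt(max(abs(res$estimates$value) / (3 * res$estimates$se)), 1)
})

test_that("toy lobule cells store consistent tripods and tensors", {
  lob <- get_toy_lobule(seed = 1L, lambda_star = 2)
  expect_gt(nrow(lob$cells), 500)
  # tensors rebuild from tripods with the configured eigenvalue weights
  i <- 7L
  nvec <- as.numeric(lob$cells[i, c("nx", "ny", "nz")])
  mvec <- as.numeric(lob$cells[i, c("mx", "my", "mz")])
  lvec <- as.numeric(lob$cells[i, c("lx", "ly", "lz")])
  A <- lob$truth$alpha1 * tcrossprod(mvec) +
    lob$truth$alpha2 * tcrossprod(nvec) +
    (-lob$truth$alpha1 - lob$truth$alpha2) * tcrossprod(lvec)
  expect_equal(as.numeric(lob$cells[i, tensor_comp_cols]),
               A[upper.tri(A, diag = TRUE)][c(1, 2, 4, 3, 5, 6)],
               tolerance = 1e-9)
  # polarity ordered towards the local plane axis (lambda* = 2, alpha2 < 0)
  keep <- !lob$field$empty & !lob$field$degenerate
  res <- coop_vs_tensors(lob$cells[keep, tripod_cols],
                         lob$field[keep, tensor_comp_cols],
                         n_boot = 100, seed = 1)
  expect_gt(res$estimates$value[1], 0)
})

test_that("local references beat a global frame on the curved toy lobule", {
  # strong coupling so the curved director field is visible above noise
  lob <- synth_toy_lobule(seed = 56, lambda_star = 30, z_layers = 3L,
                          lattice = 12)
  cells <- lob$cells
  tri <- cells[, tripod_cols]
  # local punctured-kernel reference field from the polarity tensors
  refs_local <- local_reference_field(cells, sigma = 20)
  ok <- !refs_local$degenerate
  co_local <- coop(tri[ok, ], refs_local[ok, 1:9],
                   n_boot = 0)$estimates$value[1]
  # single global frame from the grand mean tensor (curvature averages out)
  mats <- nematiq:::tensor_list(cells[, tensor_comp_cols])
  grand <- Reduce(`+`, mats) / length(mats)
  refs_global <- reference_frames_from_tensors(list(grand))
  co_global <- coop(tri, refs_global[rep(1, nrow(tri)), 1:9],
                    n_boot = 0)$estimates$value[1]
  expect_gt(co_local, co_global)
})
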
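test_that("synth_endmembers produces unit-sum overlapping spectra with a cosine table", {
  M1 <- synth_endmembers(C = 32, R = 1)
  expect_equal(sum(M1), 1)

  M <- synth_endmembers(C = 32, R = 13)
  expect_equal(unname(colSums(M)), rep(1, 13), tolerance = 1e-12)
  ct <- attr(M, "cosines")
  expect_equal(dim(ct), c(13L, 13L))
  expect_equal(unname(diag(ct)), rep(1, 13), tolerance = 1e-12)

  # direct dot-product verification of the reported cosine table
  cos_direct <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_equal(ct[2, 7], cos_direct(M[, 2], M[, 7]), tolerance = 1e-12)

  # correlated pair construction reaches the requested cosine
  Mc <- synth_endmembers(C = 32, R = 13, min_cos = 0.9, pair = c(6, 7))
  expect_gte(cos_direct(Mc[, 6], Mc[, 7]), 0.9)
  expect_error(synth_endmembers(min_cos = 1.5), "min_cos")
})

test_that("simulate_window_abundances draws U(0,1) on the active set only", {
  spec <- simulation_spec(R = 13, active = c(2, 7), seed = 99)
  A <- simulate_window_abundances(spec)
  expect_equal(dim(A), c(13L, 9L))
  expect_true(all(A[-c(2, 7), ] == 0))
  expect_true(all(A[c(2, 7), ] > 0 & A[c(2, 7), ] <= 1))
  expect_identical(A, simulate_window_abundances(spec))
  expect_error(simulation_spec(R = 5, active = c(1, 9)), "1..R")
})

test_that("apply_poisson_noise implements the shot-noise SNR convention", {
  # mean of positive entries 1 -> s = snr^2
  X <- matrix(c(0, 0.5, 1.5, 1), 2, 2)
  nz <- apply_poisson_noise(X, snr = 5, seed = 1)
  expect_equal(nz$s, 25)
  expect_true(all(nz$Y[X == 0] == 0))
  expect_error(apply_poisson_noise(matrix(0, 2, 2), 5), "all zero")

  # Monte-Carlo: at a cell with rate 25, mean/sd ~= 5
  draws <- withr::with_seed(2, rpois(10000, 25))
  mc <- apply_poisson_noise(matrix(1, 100, 100), snr = 5, seed = 2)
  expect_equal(mean(mc$Y), 25, tolerance = 0.02)
  expect_equal(mean(mc$Y) / sd(mc$Y), 5, tolerance = 0.05)
})

test_that("run_simulation_study returns a tidy reproducible table", {
  M <- synth_endmembers(C = 8, R = 4, width = 3)
  spec <- simulation_spec(C = 8, R = 4, active = c(1, 3), n_reps = 4,
                          seed = 7)
  cfg <- solver_config(tol = 1e-4, max_iter = 100L)
  res <- run_simulation_study(M, spec, snrs = c(3, 8),
                              methods = c("nls", "slpru"),
                              grid1 = c(0, 0.1), grid2 = c(0, 1), cfg = cfg)
  expect_equal(nrow(res), 4L)
  expect_setequal(names(res)[1:6], c("snr", "method", "lambda1", "lambda2",
                                     "mean_rmse", "sd_rmse"))
  expect_true(all(res$mean_rmse > 0))
  res2 <- run_simulation_study(M, spec, snrs = c(3, 8),
                               methods = c("nls", "slpru"),
                               grid1 = c(0, 0.1), grid2 = c(0, 1), cfg = cfg)
  expect_identical(res, res2)
  # grid attribute covers the full sweep
  gr <- attr(res, "grid_results")
  expect_equal(sum(gr$method == "slpru"), 2L * 4L)

  # near-noiseless limit: plain Poisson regression drives RMSE toward 0
  resh <- run_simulation_study(M, simulation_spec(C = 8, R = 4,
                                                  active = c(1, 3),
                                                  n_reps = 2, seed = 8),
                               snrs = 300, methods = "slpru",
                               grid1 = 0, grid2 = 0,
                               cfg = solver_config(tol = 1e-6,
                                                   max_iter = 2000L))
  expect_lt(resh$mean_rmse, 0.01)
})

test_that("simulate_reference_image builds a blob world that PNMF inverts", {
  m <- as.numeric(synth_endmembers(C = 16, R = 1))
  ref <- simulate_reference_image(m, shape = c(10, 10), fg_fraction = 1,
                                  snr = 10, seed = 3)
  expect_true(all(attr(ref, "fg")))
  expect_identical(ref$counts,
                   simulate_reference_image(m, shape = c(10, 10),
                                            fg_fraction = 1, snr = 10,
                                            seed = 3)$counts)

  # near-noiseless round trip: PNMF recovers the planted spectrum
  ref2 <- simulate_reference_image(m, shape = c(12, 12), fg_fraction = 0.5,
                                   snr = 60, seed = 4)
  fit <- fit_rank1_pnmf(matrix(ref2$counts, nrow = 16))
  cosd <- 1 - sum(fit$m * m) / sqrt(sum(fit$m^2) * sum(m^2))
  expect_lt(cosd, 1e-3)
})
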
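cfg0 <- solver_config(tol = 1e-8, max_iter = 5000L)

test_that("solve_window_slpru handles degenerate and noiseless windows", {
  set.seed(61)
  M <- random_endmembers(8, 4)

  # all-zero window: fidelity is minimized at A = 0 and penalties vanish
  fit <- solve_window_slpru(matrix(0, 8, 9), M,
                            solver_config(lambda1 = 0.5, lambda2 = 0.5))
  expect_equal(max(abs(fit$A)), 0, tolerance = 1e-8)

  # lambda1 = lambda2 = 0 on noiseless identifiable data recovers the truth;
  # cross-checked against an independent projected-gradient oracle
  A0 <- matrix(runif(4 * 9) * 2, 4, 9)
  Y <- M %*% A0
  fit <- solve_window_slpru(Y, M, cfg0)
  expect_lt(norm(fit$A - A0, "F") / norm(A0, "F"), 1e-3)
  Apg <- oracle_pg_poisson(Y, M, iters = 3000L)
  expect_lt(norm(Apg - A0, "F") / norm(A0, "F"), 1e-2)

  expect_error(solve_window_slpru(Y[1:3, ], M, cfg0), "channel mismatch")
})

test_that("fixed-weight window solutions match the independent splitting oracle", {
  set.seed(62)
  M <- random_endmembers(8, 4)
  A0 <- matrix(runif(4 * 9) * 3, 4, 9)
  Y <- matrix(rpois(72, M %*% A0 * 3), 8, 9)
  cfg <- solver_config(lambda1 = 0.1, lambda2 = 0.1, tol = 1e-9,
                       max_iter = 30000L, outer_reweights = 1L)
  fit <- solve_window_slpru(Y, M, cfg,
                            weights = list(wp = rep(1, 4), wq = rep(1, 4)))
  Ao <- oracle_splitting(Y, M, 0.1, 0.1, poisson = TRUE, iters = 10000L)
  oa <- oracle_objective(fit$A, M, Y, 0.1, 0.1, TRUE)
  oo <- oracle_objective(Ao, M, Y, 0.1, 0.1, TRUE)
  expect_lt(abs(oa - oo) / abs(oo), 1e-4)
})

test_that("update_weights implements inverse-magnitude reweighting", {
  A <- rbind(c(1, 2, 2), c(0, 0, 0))
  w <- update_weights(A)
  expect_equal(w$wq[2], 1 / max(1e-3 * 3, 1e-3))       # zero row: max weight
  expect_equal(which.max(w$wq), 2L)

  # scale leaves weight ratios unchanged
  w2 <- update_weights(10 * A)
  expect_equal(w$wq[1] / w$wq[2], w2$wq[1] / w2$wq[2], tolerance = 1e-10)

  # wp from sigma = (3, 1), non-decreasing with descending sigma
  Ad <- cbind(diag(c(3, 1)), matrix(0, 2, 7))
  wd <- update_weights(Ad)
  expect_equal(wd$wp, c(1 / (3 + 3e-3), 1 / (1 + 3e-3)), tolerance = 1e-12)
  expect_false(is.unsorted(wd$wp))
})

test_that("nls_pixel solves NNLS exactly (KKT-checked)", {
  set.seed(63)
  M <- random_endmembers(6, 3)
  a0 <- runif(3)
  expect_equal(nls_pixel(M %*% a0, M), a0, tolerance = 1e-8)
  expect_equal(nls_pixel(rep(0, 6), M), rep(0, 3))

  # active constraint case: unconstrained optimum is infeasible
  M2 <- rbind(c(1, 1), c(0, 1))
  a <- nls_pixel(c(0, 1), M2)
  expect_equal(a, c(0, 0.5), tolerance = 1e-10)

  # KKT residual on random problems: gradient >= 0, complementary slackness
  for (k in 1:10) {
    Mk <- matrix(runif(12), 4, 3)
    y <- runif(4)
    ak <- nls_pixel(y, Mk)
    g <- crossprod(Mk, Mk %*% ak - y)
    expect_true(all(g > -1e-8))
    expect_lt(abs(sum(g * ak)), 1e-8)
  }
})

test_that("snls/slnls reduce correctly at the ends of the penalty range", {
  set.seed(64)
  M <- random_endmembers(8, 4)
  Y <- matrix(rpois(72, 5), 8, 9)
  cfg <- solver_config(tol = 1e-9, max_iter = 20000L)

  A <- snls_window(Y, M, lambda = 0, cfg)
  Anls <- sapply(seq_len(9), function(j) nls_pixel(Y[, j], M))
  expect_equal(A, Anls, tolerance = 1e-5)

  Abig <- snls_window(Y, M, lambda = 1e6 * max(crossprod(M, Y)), cfg)
  expect_equal(max(abs(Abig)), 0, tolerance = 1e-6)

  expect_equal(slnls_window(Y, M, 0, 0, cfg), Anls, tolerance = 1e-5)

  # rank-1 noiseless data with a small nuclear penalty stays numerical rank 1
  m1 <- matrix(runif(4), 4, 1)
  a1 <- matrix(runif(9), 1, 9)
  Yr <- M %*% (m1 %*% a1) * 10
  Ar <- slnls_window(Yr, M, lambda1 = 0.05, lambda2 = 0, cfg)
  sv <- svd(Ar)$d
  expect_lt(sv[2] / sv[1], 1e-3)
})

test_that("gaussian-loss windows match splitting and proximal-gradient oracles", {
  set.seed(65)
  M <- random_endmembers(8, 4)
  A0 <- matrix(runif(36) * 2, 4, 9)
  Y <- M %*% A0 + matrix(rnorm(72, sd = 0.3), 8, 9)
  Y <- pmax(Y, 0)
  cfg <- solver_config(tol = 1e-9, max_iter = 30000L)

  Ahat <- snls_window(Y, M, lambda = 0.2, cfg)
  Apg <- oracle_pg_snls(Y, M, 0.2, iters = 10000L)
  oa <- oracle_objective(Ahat, M, Y, 0, 0.2, FALSE)
  oo <- oracle_objective(Apg, M, Y, 0, 0.2, FALSE)
  expect_lt(abs(oa - oo) / abs(oo), 1e-4)

  Ahat2 <- slnls_window(Y, M, 0.2, 0.2, cfg)
  Adr <- oracle_splitting(Y, M, 0.2, 0.2, poisson = FALSE, iters = 10000L)
  oa2 <- oracle_objective(Ahat2, M, Y, 0.2, 0.2, FALSE)
  oo2 <- oracle_objective(Adr, M, Y, 0.2, 0.2, FALSE)
  expect_lt(abs(oa2 - oo2) / abs(oo2), 1e-4)
})

test_that("l21 norm of the solution is non-increasing in lambda2", {
  set.seed(66)
  M <- random_endmembers(8, 4)
  Y <- matrix(rpois(72, 6), 8, 9)
  cfg <- solver_config(tol = 1e-8, max_iter = 10000L)
  norms <- vapply(c(0, 1e-3, 1e-2, 1e-1, 1, 10), function(l2)
    l21_norm(slnls_window(Y, M, 0, l2, cfg)), numeric(1))
  expect_true(all(diff(norms) <= 1e-6 * pmax(1, norms[-length(norms)])))
})

test_that("solvers are deterministic given identical inputs", {
  set.seed(67)
  M <- random_endmembers(8, 4)
  Y <- matrix(rpois(72, 5), 8, 9)
  cfg <- solver_config(lambda1 = 0.1, lambda2 = 1)
  f1 <- solve_window_slpru(Y, M, cfg)
  f2 <- solve_window_slpru(Y, M, cfg)
  expect_identical(f1$A, f2$A)
  expect_identical(snls_window(Y, M, 0.5), snls_window(Y, M, 0.5))
})
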
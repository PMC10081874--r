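test_that("average_proportion follows the proportion formula", {
  expect_equal(average_proportion(matrix(c(1, 0, 0), 3, 1), 1), 1)
  expect_equal(average_proportion(matrix(c(1, 1, 0), 3, 1), 1), 0.5)
  expect_equal(average_proportion(cbind(c(1, 0), c(1, 3)), 1), 0.625)

  # proportions over all endmembers sum to 1 at every masked pixel
  set.seed(81)
  A <- matrix(runif(5 * 8) + 0.01, 5, 8)
  tot <- vapply(1:5, function(r) average_proportion(A, r), numeric(1))
  expect_equal(sum(tot * 1), sum(colMeans(t(A) / colSums(A))), tolerance = 1e-12)
  expect_equal(sum(vapply(1:5, function(r) average_proportion(A, r),
                          numeric(1))), 1, tolerance = 1e-12)

  expect_error(average_proportion(A, 1, integer(0)), "empty mask")
  expect_error(average_proportion(cbind(c(0, 0)), 1), "zero total")
})

test_that("rmse is the root of the mean squared Frobenius error and a metric", {
  A <- diag(2)
  expect_equal(rmse(A, A), 0)
  expect_equal(rmse(A, matrix(0, 2, 2)), sqrt(2 / 4))
  set.seed(82)
  X <- matrix(rnorm(12), 3, 4); Y <- matrix(rnorm(12), 3, 4)
  Z <- matrix(rnorm(12), 3, 4)
  loop <- 0
  for (i in 1:3) for (j in 1:4) loop <- loop + (X[i, j] - Y[i, j])^2
  expect_equal(rmse(X, Y), sqrt(loop / 12), tolerance = 1e-12)
  expect_equal(rmse(X, Y), rmse(Y, X))
  expect_lte(rmse(X, Z), rmse(X, Y) + rmse(Y, Z) + 1e-12)
  expect_error(rmse(X, Y[, 1:2]), "equal shape")
})

test_that("otsu_threshold equals exhaustive between-class variance search", {
  x <- c(rep(0, 30), rep(10, 30))
  t0 <- otsu_threshold(x)
  expect_gt(t0, 0); expect_lt(t0, 10)

  brute_otsu <- function(values, bins = 256L) {
    lo <- min(values); hi <- max(values)
    bw <- (hi - lo) / bins
    idx <- pmin(pmax(floor((values - lo) / bw), 0), bins - 1L) + 1L
    cnt <- tabulate(idx, bins)
    mids <- lo + (seq_len(bins) - 0.5) * bw
    best <- -Inf; kb <- 1L
    for (k in 1:(bins - 1L)) {
      w0 <- sum(cnt[1:k]); w1 <- sum(cnt) - w0
      if (w0 == 0 || w1 == 0) next
      m0 <- sum(cnt[1:k] * mids[1:k]) / w0
      m1 <- sum(cnt[(k + 1):bins] * mids[(k + 1):bins]) / w1
      v <- w0 * w1 * (m0 - m1)^2
      if (v > best) { best <- v; kb <- k }
    }
    lo + kb * bw
  }
  set.seed(83)
  for (k in 1:5) {
    x <- c(rnorm(200, 2), rnorm(100, 9, 2))
    expect_equal(otsu_threshold(x), brute_otsu(x), tolerance = 1e-12)
    # scale equivariance within one bin width
    expect_lt(abs(otsu_threshold(3 * x) - 3 * otsu_threshold(x)),
              3 * diff(range(x)) / 256 + 1e-9)
  }
  expect_error(otsu_threshold(rep(4, 10)), "distinct")
})

test_that("triangle_threshold matches a direct geometric recomputation", {
  set.seed(84)
  x <- rexp(3000)
  t0 <- triangle_threshold(x)
  # falls between the peak and the tail end
  h <- hist(x, breaks = seq(min(x), max(x), length.out = 257), plot = FALSE)
  peak_mid <- h$mids[which.max(h$counts)]
  expect_gt(t0, peak_mid - diff(range(x)) / 256)
  expect_lt(t0, max(x))

  # independent geometry oracle on the same 256-bin histogram
  brute_triangle <- function(values, bins = 256L) {
    lo <- min(values); hi <- max(values)
    bw <- (hi - lo) / bins
    idx <- pmin(pmax(floor((values - lo) / bw), 0), bins - 1L) + 1L
    cnt <- tabulate(idx, bins)
    peak <- which.max(cnt)
    nz <- range(which(cnt > 0))
    right <- (nz[2] - peak) >= (peak - nz[1])
    end <- if (right) nz[2] else nz[1]
    ks <- if (right) peak:end else end:peak
    best <- -Inf; kb <- peak
    for (k in ks) {
      # distance of (k, cnt[k]) from the peak--end chord
      d <- abs((cnt[end] - cnt[peak]) * (k - peak) -
                 (end - peak) * (cnt[k] - cnt[peak])) /
        sqrt((end - peak)^2 + (cnt[end] - cnt[peak])^2)
      if (d > best) { best <- d; kb <- k }
    }
    lo + kb * bw
  }
  for (k in 1:5) {
    x <- c(rexp(2000, 0.7), runif(100, 5, 8))
    expect_equal(triangle_threshold(x), brute_triangle(x), tolerance = 1e-12)
  }
  expect_error(triangle_threshold(rep(1, 5)), "distinct")
})

test_that("circularity separates disks from squares and bars", {
  mk_disk <- function(r, size = 2 * r + 20) {
    ctr <- size / 2
    outer(1:size, 1:size, function(i, j) (i - ctr)^2 + (j - ctr)^2 < r^2)
  }
  d <- circularity(mk_disk(50))
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$circularity - 1), 0.1)

  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  s <- circularity(sq)
  expect_equal(s$area, 100L)
  expect_lt(abs(s$circularity - pi / 4), 0.1 * pi / 4)

  # translation invariance
  sq2 <- matrix(FALSE, 20, 20); sq2[3:12, 8:17] <- TRUE
  expect_equal(circularity(sq2)$circularity, s$circularity, tolerance = 1e-12)

  # a same-area 1xk bar is less circular than the disk
  bar <- matrix(FALSE, 10, 110); bar[5, 3:102] <- TRUE
  expect_lt(circularity(bar)$circularity, d$circularity)

  # two disjoint disks -> two objects
  two <- matrix(FALSE, 40, 80)
  two[1:40, 1:40] <- mk_disk(10, 40)
  two[1:40, 41:80] <- mk_disk(8, 40)
  expect_equal(nrow(circularity(two)), 2L)
  expect_equal(nrow(circularity(matrix(FALSE, 5, 5))), 0L)
})

test_that("welch_t matches the direct formula and stats::t.test", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5)
  w <- welch_t(x, y)
  # textbook recomputation
  se2 <- var(x) / 3 + var(y) / 5
  t_direct <- (mean(x) - mean(y)) / sqrt(se2)
  df_direct <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 5)^2 / 4)
  expect_equal(w$t, t_direct, tolerance = 1e-12)
  expect_equal(w$df, df_direct, tolerance = 1e-12)
  tt <- t.test(x, y)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)

  # identical samples: t = 0, p = 1; swapping flips the sign only
  w0 <- welch_t(x, x)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  ws <- welch_t(y, x)
  expect_equal(ws$t, -w$t)
  expect_equal(ws$p, w$p)

  expect_error(welch_t(1, y), "at least 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})
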
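# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (scalar loops, generic 1-D minimization, a different
# splitting algorithm) and share no code with the package internals.

# Scalar-loop objective evaluator for the windowed unmixing problem.
oracle_objective <- function(A, M, Y, lambda1 = 0, lambda2 = 0,
                             poisson = TRUE, wp = NULL, wq = NULL) {
  A <- pmax(A, 0)
  MA <- M %*% A
  fid <- 0
  if (poisson) {
    for (i in seq_len(nrow(Y))) for (j in seq_len(ncol(Y))) {
      r <- MA[i, j]; y <- Y[i, j]
      fid <- fid + r - (if (y > 0) y * log(max(r, 1e-12)) else 0)
    }
  } else {
    for (i in seq_len(nrow(Y))) for (j in seq_len(ncol(Y)))
      fid <- fid + 0.5 * (Y[i, j] - MA[i, j])^2
  }
  sv <- svd(A)$d
  if (is.null(wp)) wp <- rep(1, length(sv))
  rn <- apply(A, 1L, function(r) sqrt(sum(r^2)))
  if (is.null(wq)) wq <- rep(1, length(rn))
  fid + lambda1 * sum(wp[seq_along(sv)] * sv) + lambda2 * sum(wq * rn)
}

# Product-space Douglas-Rachford oracle for
#   min_{A>=0} loss(MA; Y) + lambda1 ||A||_* + lambda2 ||A||_{2,1}
# Variables (A1, A2, Z) constrained to the subspace {(A, A, MA)}; blockwise
# proxes (SVT; nonneg group-shrink; loss prox). A long fixed run stands in
# for an exact convex solver.
oracle_splitting <- function(Y, M, lambda1 = 0, lambda2 = 0, poisson = TRUE,
                             iters = 50000L, gamma = 1) {
  R <- ncol(M); N <- ncol(Y)
  Kinv <- solve(2 * diag(R) + crossprod(M))
  u1 <- matrix(0, R, N); u2 <- matrix(0, R, N); uz <- Y
  proj <- function(B1, B2, Wl) Kinv %*% (B1 + B2 + crossprod(M, Wl))
  for (k in seq_len(iters)) {
    A <- proj(u1, u2, uz)
    MA <- M %*% A
    r1 <- 2 * A - u1; r2 <- 2 * A - u2; rz <- 2 * MA - uz
    y1 <- if (lambda1 > 0) {
      sv <- svd(r1)
      sv$u %*% (pmax(sv$d - gamma * lambda1, 0) * t(sv$v))
    } else r1
    p2 <- pmax(r2, 0)
    rn <- sqrt(rowSums(p2^2))
    y2 <- p2 * ifelse(rn > 0, pmax(0, 1 - gamma * lambda2 / rn), 0)
    yz <- if (poisson) {
      t0 <- rz - gamma
      0.5 * (t0 + sqrt(t0^2 + 4 * gamma * Y))
    } else (rz + gamma * Y) / (1 + gamma)
    u1 <- u1 + y1 - A
    u2 <- u2 + y2 - A
    uz <- uz + yz - MA
  }
  pmax(proj(u1, u2, uz), 0)
}

# Long-run proximal gradient for the Gaussian-loss l2,1 problem (S-NLS):
# smooth part (1/2)||Y - MA||_F^2, prox part lambda ||A||_{2,1} + ind(A>=0).
oracle_pg_snls <- function(Y, M, lambda, iters = 50000L) {
  L <- max(svd(M)$d)^2
  step <- 1 / L
  A <- matrix(0, ncol(M), ncol(Y))
  for (k in seq_len(iters)) {
    G <- crossprod(M, M %*% A - Y)
    V <- pmax(A - step * G, 0)
    rn <- sqrt(rowSums(V^2))
    A <- V * ifelse(rn > 0, pmax(0, 1 - step * lambda / rn), 0)
  }
  A
}

# Projected gradient with backtracking on the pure Poisson NLL (lambda = 0).
oracle_pg_poisson <- function(Y, M, iters = 5000L, A0 = NULL) {
  R <- ncol(M); N <- ncol(Y)
  A <- if (is.null(A0)) matrix(mean(Y), R, N) else A0
  f <- function(A) {
    MA <- pmax(M %*% A, 1e-12)
    sum(MA) - sum(ifelse(Y > 0, Y * log(MA), 0))
  }
  fa <- f(A)
  step <- 1
  for (k in seq_len(iters)) {
    MA <- pmax(M %*% A, 1e-12)
    G <- crossprod(M, 1 - Y / MA)
    repeat {
      A2 <- pmax(A - step * G, 0)
      fa2 <- f(A2)
      if (fa2 <= fa + 1e-12 || step < 1e-14) break
      step <- step / 2
    }
    if (max(abs(A2 - A)) < 1e-12) { A <- A2; break }
    A <- A2; fa <- fa2
    step <- step * 1.5
  }
  A
}

# Golden-section search for a 1-D minimum on [lo, hi].
golden_min <- function(fn, lo, hi, tol = 1e-10) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - phi * (b - a); d <- a + phi * (b - a)
  while (abs(b - a) > tol) {
    if (fn(c) < fn(d)) b <- d else a <- c
    c <- b - phi * (b - a); d <- a + phi * (b - a)
  }
  (a + b) / 2
}

# Random unit-column-sum non-negative matrix.
random_endmembers <- function(C, R) {
  M <- matrix(runif(C * R) + 0.05, C, R)
  sweep(M, 2L, colSums(M), "/")
}

# Replicate-pad-then-slice oracle for window extraction.
oracle_window <- function(counts, r, cc) {
  d <- dim(counts)
  Y <- matrix(0, d[1L], 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    rr <- min(max(r + dr, 1L), d[2L])
    c2 <- min(max(cc + dc, 1L), d[3L])
    Y[, k] <- counts[, rr, c2]
  }
  Y
}
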
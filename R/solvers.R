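## Window solvers: SL-PRU (weighted Poisson ADMM with reweighting) and the
## least-squares baselines NLS, S-NLS, SL-NLS.

as_window_matrix <- function(Y) {
  if (inherits(Y, "slpru_window")) Y <- Y$Y
  check_counts_matrix(as.matrix(Y))
}

weighted_l21_norm <- function(A, wq) {
  sum(wq * sqrt(rowSums(A^2)))
}

#' Solve one window with SL-PRU
#'
#' Minimizes the Poisson negative log-likelihood plus `lambda1` times the
#' weighted nuclear norm and `lambda2` times the weighted l2,1 norm over
#' non-negative abundances, by a four-block ADMM (splits for the fidelity,
#' each penalty, and the non-negativity constraint). `cfg$outer_reweights`
#' outer passes are run: the first with uniform weights, later ones with
#' inverse-magnitude weights from [update_weights()].
#'
#' @param Y a window from [extract_windows()] or a C x N count matrix.
#' @param M an [endmember_matrix()] (C x R).
#' @param cfg a [solver_config()]; `cfg$lambda1`, `cfg$lambda2` are the
#'   penalty weights.
#' @param weights optional `list(wp =, wq =)` of fixed penalty weights; when
#'   given, the adaptive reweighting schedule is bypassed and a single ADMM
#'   run solves the (convex, fixed-weight) problem. `wp` must be
#'   non-decreasing when paired with descending singular values.
#' @return list of class `slpru_fit`: `A` (R x N, >= 0), `objective`
#'   (the penalized objective at the final weights), `iterations` (last ADMM
#'   pass), `primal_residual`, `dual_residual`, `converged`, `weights`.
#' @export
solve_window_slpru <- function(Y, M, cfg = solver_config(), weights = NULL) {
  Y <- as_window_matrix(Y)
  M <- as.matrix(M)
  if (nrow(Y) != nrow(M))
    stop("channel mismatch between `Y` and `M`", call. = FALSE)
  wp_fixed <- wq_fixed <- numeric(0)
  if (!is.null(weights)) {
    wp_fixed <- as.numeric(weights$wp)
    wq_fixed <- as.numeric(weights$wq)
    if (any(c(wp_fixed, wq_fixed) < 0))
      stop("weights must be non-negative", call. = FALSE)
    if (is.unsorted(wp_fixed))
      stop("`wp` must be non-decreasing along descending singular values",
           call. = FALSE)
  }
  fit <- admm_window_cpp(Y, M, cfg$lambda1, cfg$lambda2, cfg$mu, cfg$tol,
                         cfg$max_iter, cfg$outer_reweights, cfg$eps_scale,
                         TRUE, TRUE, wp_fixed, wq_fixed)
  obj <- poisson_nll(M, fit$A, Y, cfg$log_guard) +
    cfg$lambda1 * weighted_nuclear_norm(fit$A, fit$wp) +
    cfg$lambda2 * weighted_l21_norm(fit$A, fit$wq)
  structure(list(A = fit$A, objective = obj, iterations = fit$iterations,
                 primal_residual = fit$primal_residual,
                 dual_residual = fit$dual_residual,
                 converged = fit$converged,
                 weights = list(wp = fit$wp, wq = fit$wq)),
            class = "slpru_fit")
}

#' Inverse-magnitude reweighting rule
#'
#' Singular-value weights `wp_i = 1 / (sigma_i(A) + eps_p)` with
#' `eps_p = eps_scale * max(sigma_1(A), 1)`, and row weights
#' `wq_r = 1 / (||a_r||_2 + eps_q)` with
#' `eps_q = max(eps_scale * max_r ||a_r||_2, eps_scale)`. Paired with
#' descending singular values, `wp` is non-decreasing, as the weighted SVT
#' prox requires.
#'
#' @param A non-negative abundance matrix.
#' @param eps_scale relative floor, > 0.
#' @return list with fields `wp` and `wq`.
#' @export
update_weights <- function(A, eps_scale = 1e-3) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("`A` must be non-negative", call. = FALSE)
  s <- svd(A, nu = 0, nv = 0)$d
  eps_p <- eps_scale * max(s[1L], 1)
  rn <- sqrt(rowSums(A^2))
  eps_q <- max(eps_scale * max(rn), eps_scale)
  list(wp = 1 / (s + eps_p), wq = 1 / (rn + eps_q))
}

#' Pixelwise non-negative least squares
#'
#' `argmin_{a >= 0} ||y - M a||_2^2` by the Lawson-Hanson active-set method.
#'
#' @param y non-negative C-vector.
#' @param M C x R endmember matrix.
#' @return non-negative R-vector.
#' @export
nls_pixel <- function(y, M) {
  y <- as.numeric(y)
  M <- as.matrix(M)
  if (any(y < 0)) stop("`y` must be non-negative", call. = FALSE)
  if (length(y) != nrow(M))
    stop("channel mismatch between `y` and `M`", call. = FALSE)
  as.numeric(nnls_cpp(M, y))
}

#' Sparse NLS on a window
#'
#' Approximately minimizes `(1/2)||Y - MA||_F^2 + lambda ||A||_{2,1}` over
#' `A >= 0` using the same ADMM skeleton as SL-PRU with the squared-loss prox
#' replacing the Poisson prox (unweighted, single pass).
#'
#' @param Y window or C x N count matrix.
#' @param M C x R endmember matrix.
#' @param lambda l2,1 penalty weight, >= 0.
#' @param cfg a [solver_config()] supplying `mu`, `tol`, `max_iter`.
#' @return R x N non-negative abundance matrix.
#' @export
snls_window <- function(Y, M, lambda = 0, cfg = solver_config()) {
  Y <- as_window_matrix(Y)
  M <- as.matrix(M)
  if (nrow(Y) != nrow(M))
    stop("channel mismatch between `Y` and `M`", call. = FALSE)
  admm_window_cpp(Y, M, 0, lambda, cfg$mu, cfg$tol, cfg$max_iter,
                  1L, cfg$eps_scale, FALSE, FALSE,
                  numeric(0), numeric(0))$A
}

#' Sparse and low-rank NLS on a window
#'
#' Approximately minimizes
#' `(1/2)||Y - MA||_F^2 + lambda1 ||A||_* + lambda2 ||A||_{2,1}`, `A >= 0`
#' (unweighted norms), via the ADMM skeleton.
#'
#' @inheritParams snls_window
#' @param lambda1 nuclear-norm penalty weight, >= 0.
#' @param lambda2 l2,1 penalty weight, >= 0.
#' @return R x N non-negative abundance matrix.
#' @export
slnls_window <- function(Y, M, lambda1 = 0, lambda2 = 0,
                         cfg = solver_config()) {
  Y <- as_window_matrix(Y)
  M <- as.matrix(M)
  if (nrow(Y) != nrow(M))
    stop("channel mismatch between `Y` and `M`", call. = FALSE)
  admm_window_cpp(Y, M, lambda1, lambda2, cfg$mu, cfg$tol, cfg$max_iter,
                  1L, cfg$eps_scale, FALSE, FALSE, numeric(0), numeric(0))$A
}
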
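## Closed-form proximal operators used by the SL-PRU splitting scheme.
## These R implementations define the module surface; the compiled ADMM core
## carries equivalent inline versions (their agreement is covered by the
## convex-oracle equivalence tests).

#' Proximal operator of the Poisson fidelity term
#'
#' Elementwise solves `argmin_z z - y log z + (rho/2)(z - v)^2`, i.e.
#' `z = ((v - 1/rho) + sqrt((v - 1/rho)^2 + 4 y / rho)) / 2`. Entries with
#' `y = 0` reduce to `max(v - 1/rho, 0)`.
#'
#' @param V numeric matrix of inputs.
#' @param Y non-negative count matrix, same shape as `V`.
#' @param rho prox penalty, > 0.
#' @return matrix of the same shape.
#' @export
prox_poisson <- function(V, Y, rho) {
  V <- as.matrix(V); Y <- as.matrix(Y)
  if (!isTRUE(all(dim(V) == dim(Y))))
    stop("`V` and `Y` must have equal shape", call. = FALSE)
  if (rho <= 0) stop("`rho` must be positive", call. = FALSE)
  check_counts_matrix(Y)
  t <- V - 1 / rho
  0.5 * (t + sqrt(t^2 + 4 * Y / rho))
}

#' Proximal operator of the weighted nuclear norm (weighted SVT)
#'
#' `argmin_Z tau * ||Z||_{wp,*} + (1/2)||Z - V||_F^2` via singular value
#' thresholding `sigma_i -> max(sigma_i - tau * wp_i, 0)`. This closed form is
#' the exact prox only when `wp` is non-decreasing along descending singular
#' values, which is enforced.
#'
#' @param V numeric matrix.
#' @param wp non-negative, non-decreasing weights (one per singular value).
#' @param tau threshold scale, >= 0.
#' @return matrix of the same shape.
#' @export
prox_weighted_nuclear <- function(V, wp = NULL, tau = 0) {
  V <- as.matrix(V)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  if (tau == 0) return(V)
  sv <- svd(V)
  k <- length(sv$d)
  if (is.null(wp)) wp <- rep(1, k)
  if (any(wp < 0)) stop("weights must be non-negative", call. = FALSE)
  if (length(wp) < k) stop("need one weight per singular value", call. = FALSE)
  wp <- wp[seq_len(k)]
  if (is.unsorted(wp, strictly = FALSE))
    stop("`wp` must be non-decreasing along descending singular values",
         call. = FALSE)
  d <- pmax(sv$d - tau * wp, 0)
  sv$u %*% (d * t(sv$v))
}

#' Proximal operator of the weighted l2,1 norm (row-wise group shrinkage)
#'
#' Row r of the result is `max(0, 1 - tau * wq_r / ||v_r||_2) * v_r`; a zero
#' row stays zero.
#'
#' @param V numeric matrix.
#' @param wq non-negative row weights, length `nrow(V)`.
#' @param tau threshold scale, >= 0.
#' @return matrix of the same shape.
#' @export
prox_weighted_l21 <- function(V, wq = NULL, tau = 0) {
  V <- as.matrix(V)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  if (is.null(wq)) wq <- rep(1, nrow(V))
  if (length(wq) != nrow(V))
    stop("`wq` must have one weight per row", call. = FALSE)
  if (any(wq < 0)) stop("weights must be non-negative", call. = FALSE)
  rn <- sqrt(rowSums(V^2))
  shrink <- ifelse(rn > 0, pmax(0, 1 - tau * wq / rn), 0)
  V * shrink
}

#' Projection onto the non-negative orthant
#'
#' @param V numeric matrix.
#' @return `pmax(V, 0)`.
#' @export
project_nonneg <- function(V) {
  pmax(as.matrix(V), 0)
}
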
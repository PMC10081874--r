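## Core domain types and shared math: spectral images, endmember and
## abundance matrices, solver configuration, objective terms, windows.

#' Construct a spectral image
#'
#' A spectral image is a channels-first cube of non-negative photon counts:
#' `counts[c, h, w]` is the count recorded in spectral channel `c` at pixel
#' `(h, w)`.
#'
#' @param counts numeric array, C x H x W, all entries >= 0. A C x N matrix is
#'   also accepted and treated as C x N x 1.
#' @param channel_centers optional numeric vector of channel centre
#'   wavelengths in nm, length C.
#' @return an object of class `spectral_image` with fields `counts` and
#'   `channel_centers`.
#' @export
spectral_image <- function(counts, channel_centers = NULL) {
  if (is.matrix(counts)) counts <- array(counts, c(dim(counts), 1L))
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a C x H x W array", call. = FALSE)
  if (any(!is.finite(counts)))
    stop("`counts` contains non-finite values", call. = FALSE)
  if (any(counts < 0))
    stop("`counts` must be non-negative", call. = FALSE)
  if (any(dim(counts) < 1L))
    stop("all dimensions of `counts` must be >= 1", call. = FALSE)
  if (!is.null(channel_centers) && length(channel_centers) != dim(counts)[1L])
    stop("`channel_centers` must have length C", call. = FALSE)
  structure(list(counts = counts, channel_centers = channel_centers),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<spectral_image> C=%d channels, %d x %d pixels, total counts %.6g\n",
              d[1L], d[2L], d[3L], sum(x$counts)))
  invisible(x)
}

#' Construct an endmember matrix
#'
#' Columns are fluorophore reference spectra. Columns are normalized to unit
#' sum so that abundances carry total-photon-count units and proportions are
#' scale-free.
#'
#' @param M numeric C x R matrix, entries >= 0, no all-zero column.
#' @param names optional character vector of R fluorophore labels.
#' @return a unit-column-sum matrix of class `endmember_matrix`.
#' @export
endmember_matrix <- function(M, names = NULL) {
  M <- as.matrix(M)
  if (any(!is.finite(M)) || any(M < 0))
    stop("endmember matrix must be finite and non-negative", call. = FALSE)
  cs <- colSums(M)
  if (any(cs == 0))
    stop("endmember matrix has an all-zero column", call. = FALSE)
  M <- sweep(M, 2L, cs, "/")
  if (!is.null(names)) {
    if (length(names) != ncol(M))
      stop("`names` must have one label per endmember", call. = FALSE)
    colnames(M) <- names
  } else if (is.null(colnames(M))) {
    colnames(M) <- paste0("EM", seq_len(ncol(M)))
  }
  structure(M, class = c("endmember_matrix", "matrix", "array"))
}

#' Solver configuration for the windowed unmixing problem
#'
#' @param lambda1 nuclear-norm penalty weight, >= 0.
#' @param lambda2 l2,1 penalty weight, >= 0.
#' @param mu ADMM penalty parameter, > 0 (default 0.01).
#' @param tol stopping tolerance (relative and absolute, Boyd-style), > 0.
#' @param max_iter maximum ADMM iterations per pass.
#' @param outer_reweights number of outer passes; the first uses uniform
#'   weights, later passes use inverse-magnitude reweighting.
#' @param eps_scale relative floor used in the reweighting rule.
#' @param log_guard lower clamp for log arguments in the Poisson likelihood.
#' @return a list of class `solver_config`.
#' @export
solver_config <- function(lambda1 = 0, lambda2 = 0, mu = 0.01, tol = 1e-6,
                          max_iter = 2000L, outer_reweights = 2L,
                          eps_scale = 1e-3, log_guard = 1e-12) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, mu > 0, tol > 0, max_iter >= 1,
            outer_reweights >= 1, eps_scale > 0, log_guard > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, mu = mu, tol = tol,
                 max_iter = as.integer(max_iter),
                 outer_reweights = as.integer(outer_reweights),
                 eps_scale = eps_scale, log_guard = log_guard),
            class = "solver_config")
}

check_counts_matrix <- function(Y, name = "Y") {
  if (!is.matrix(Y)) stop(sprintf("`%s` must be a matrix", name), call. = FALSE)
  if (any(!is.finite(Y)) || any(Y < 0))
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  Y
}

#' Poisson negative log-likelihood (fidelity term)
#'
#' Computes `sum((MA)_cn - Y_cn * log((MA)_cn))` with the conventions
#' `0 * log 0 = 0` and the log argument clamped below at `log_guard`.
#'
#' @param M C x R endmember matrix.
#' @param A R x N non-negative abundance matrix.
#' @param Y C x N non-negative count matrix.
#' @param log_guard lower clamp for the log argument.
#' @return a scalar; not necessarily non-negative for general inputs.
#' @export
poisson_nll <- function(M, A, Y, log_guard = 1e-12) {
  M <- as.matrix(M); A <- as.matrix(A); Y <- as.matrix(Y)
  if (ncol(M) != nrow(A) || nrow(M) != nrow(Y) || ncol(A) != ncol(Y))
    stop("non-conformable shapes in poisson_nll", call. = FALSE)
  check_counts_matrix(Y)
  if (any(A < 0)) stop("`A` must be non-negative", call. = FALSE)
  if (any(M < 0)) stop("`M` must be non-negative", call. = FALSE)
  MA <- M %*% A
  lg <- log(pmax(MA, log_guard))
  term <- Y * lg
  term[Y == 0] <- 0
  sum(MA) - sum(term)
}

#' l2,1 norm: sum of row-wise Euclidean norms
#'
#' @param A numeric matrix.
#' @return `sum_r ||A[r, ]||_2`.
#' @export
l21_norm <- function(A) {
  A <- as.matrix(A)
  sum(sqrt(rowSums(A^2)))
}

#' Weighted nuclear norm
#'
#' `sum_i wp_i * sigma_i(A)` with singular values in descending order.
#'
#' @param A numeric matrix.
#' @param wp non-negative weights, at least as many as singular values;
#'   paired with descending singular values.
#' @return a non-negative scalar.
#' @export
weighted_nuclear_norm <- function(A, wp = NULL) {
  A <- as.matrix(A)
  s <- svd(A, nu = 0, nv = 0)$d
  if (is.null(wp)) wp <- rep(1, length(s))
  if (any(wp < 0)) stop("weights must be non-negative", call. = FALSE)
  if (length(wp) < length(s))
    stop("need at least one weight per singular value", call. = FALSE)
  sum(wp[seq_along(s)] * s)
}

## Replicate-pad a C x H x W cube by one pixel on each spatial border.
pad_replicate <- function(counts) {
  d <- dim(counts)
  hi <- c(1L, seq_len(d[2L]), d[2L])
  wi <- c(1L, seq_len(d[3L]), d[3L])
  counts[, hi, wi, drop = FALSE]
}

## All 3x3 windows of an image as a C x 9 x (H*W) cube, row-major flattening
## of each patch (offsets (-1,-1), (-1,0), ..., (1,1)); centre is column 5.
## Pixels are traversed row-major: (1,1), (1,2), ..., (H,W).
window_cube <- function(img) {
  counts <- if (inherits(img, "spectral_image")) img$counts else img
  d <- dim(counts)
  C <- d[1L]; H <- d[2L]; W <- d[3L]
  P <- pad_replicate(counts)
  out <- array(0, c(C, 9L, H * W))
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    blk <- P[, (2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc), drop = FALSE]
    ## row-major pixel order: transpose the spatial dims before flattening
    out[, k, ] <- aperm(blk, c(1L, 3L, 2L))
  }
  out
}

#' Extract all 3x3 sliding windows of a spectral image
#'
#' One window per pixel; borders are handled by replicate padding so that
#' every pixel has a centred window. Window columns are the row-major
#' flattening of the 3x3 patch, so the centre pixel is column 5.
#'
#' @param img a [spectral_image()] (or C x H x W array).
#' @return a list of H*W windows in row-major pixel order; each is a list
#'   with fields `Y` (C x 9 count matrix), `center` (5, 1-based) and
#'   `origin` (`c(row, col)` of the centre pixel).
#' @export
extract_windows <- function(img) {
  counts <- if (inherits(img, "spectral_image")) img$counts else img
  d <- dim(counts)
  H <- d[2L]; W <- d[3L]
  cube <- window_cube(counts)
  idx <- 0L
  out <- vector("list", H * W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    idx <- idx + 1L
    out[[idx]] <- structure(
      list(Y = cube[, , idx, drop = TRUE], center = 5L, origin = c(r, cc)),
      class = "slpru_window")
  }
  out
}
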
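## Rank-1 Poisson NMF (generalized KL) for endmember extraction from
## single-fluorophore reference images.

#' Closed-form rank-1 generalized-KL factorization
#'
#' The rank-1 minimizer of `sum(m a' - Ym o log(m a'))` satisfies
#' `m a' = (row sums)(col sums)' / total`. Used as the independent oracle for
#' the iterative fit.
#'
#' @param Ym non-negative C x N count matrix with positive total.
#' @return list with unit-sum `m` (length C) and `a` (length N).
#' @export
rank1_kl_closed_form <- function(Ym) {
  Ym <- check_counts_matrix(as.matrix(Ym), "Ym")
  tot <- sum(Ym)
  if (tot <= 0) stop("`Ym` must have positive total count", call. = FALSE)
  rs <- rowSums(Ym)
  m <- rs / tot
  a <- colSums(Ym)
  list(m = m, a = a)
}

#' Fit a rank-1 Poisson NMF by multiplicative updates
#'
#' Alternating Lee-Seung multiplicative updates for the generalized
#' Kullback-Leibler objective `sum(m a' - Ym o log(m a'))`, `m, a >= 0`.
#' The returned `m` is normalized to unit sum with the scale folded into `a`.
#'
#' @param Ym non-negative C x N count matrix, not all zero.
#' @param tol stop when the relative objective change drops below `tol`.
#' @param max_iter iteration cap.
#' @return list of class `rank1_fit` with fields `m` (unit sum), `a`,
#'   `objective_trace` (non-increasing), `iterations`.
#' @export
fit_rank1_pnmf <- function(Ym, tol = 1e-10, max_iter = 200L) {
  Ym <- check_counts_matrix(as.matrix(Ym), "Ym")
  if (sum(Ym) <= 0)
    stop("degenerate input: `Ym` is all zero", call. = FALSE)
  C <- nrow(Ym); N <- ncol(Ym)
  eps <- 1e-12
  m <- rep(1 / C, C)
  a <- rep(sum(Ym) / N, N)
  obj <- function(m, a) {
    MA <- outer(m, a)
    lg <- log(pmax(MA, eps))
    term <- Ym * lg
    term[Ym == 0] <- 0
    sum(MA) - sum(term)
  }
  trace <- obj(m, a)
  for (it in seq_len(max_iter)) {
    MA <- pmax(outer(m, a), eps)
    m <- m * as.vector((Ym / MA) %*% a) / max(sum(a), eps)
    MA <- pmax(outer(m, a), eps)
    a <- a * as.vector(crossprod(Ym / MA, m)) / max(sum(m), eps)
    trace <- c(trace, obj(m, a))
    k <- length(trace)
    if (abs(trace[k] - trace[k - 1L]) <=
        tol * max(1, abs(trace[k - 1L]))) break
  }
  s <- sum(m)
  structure(list(m = m / s, a = a * s, objective_trace = trace,
                 iterations = length(trace) - 1L),
            class = "rank1_fit")
}

#' Extract endmembers from single-fluorophore reference images
#'
#' Each reference image is flattened to a C x N count matrix and factorized
#' by [fit_rank1_pnmf()]; column r of the result is the unit-sum spectrum of
#' reference r, in input order.
#'
#' @param refs list of [spectral_image()] objects (or C x H x W arrays), one
#'   fluorophore each. Names, if present, become fluorophore labels.
#' @param tol,max_iter passed to [fit_rank1_pnmf()].
#' @return an [endmember_matrix()].
#' @export
extract_endmembers <- function(refs, tol = 1e-10, max_iter = 200L) {
  if (!length(refs)) stop("need at least one reference image", call. = FALSE)
  cols <- lapply(seq_along(refs), function(r) {
    img <- refs[[r]]
    counts <- if (inherits(img, "spectral_image")) img$counts else img
    Ym <- matrix(counts, nrow = dim(counts)[1L])
    fit <- tryCatch(fit_rank1_pnmf(Ym, tol = tol, max_iter = max_iter),
                    error = function(e)
                      stop(sprintf("reference %d: %s", r, conditionMessage(e)),
                           call. = FALSE))
    fit$m
  })
  M <- do.call(cbind, cols)
  nm <- names(refs)
  if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("Ref", seq_along(refs))
  endmember_matrix(M, names = nm)
}
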
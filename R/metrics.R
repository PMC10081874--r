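## Evaluation metrics: average proportion, RMSE, histogram thresholds,
## connected-component circularity, Welch's t-test.

#' Average proportion of one endmember over foreground pixels
#'
#' For each masked pixel the proportion is `A[r0, n] / sum_r A[r, n]`; the
#' average proportion is the mean over the mask. On a single-fluorophore
#' reference image with `r0` its true endmember, values near 1 indicate
#' accurate unmixing.
#'
#' @param A an [abundance_image()] or an R x N abundance matrix.
#' @param r0 endmember index (1-based).
#' @param mask logical H x W matrix (for abundance images) or logical/integer
#'   pixel index vector (for matrices). Masked pixels must have positive
#'   total abundance.
#' @return scalar in `[0, 1]`.
#' @export
average_proportion <- function(A, r0, mask = NULL) {
  if (inherits(A, "abundance_image")) {
    d <- dim(A$values)
    Am <- matrix(A$values, nrow = d[1L])      # column-major pixel order
    if (is.null(mask)) mask <- rep(TRUE, d[2L] * d[3L])
    mask <- as.vector(mask)
  } else {
    Am <- as.matrix(A)
    if (is.null(mask)) mask <- rep(TRUE, ncol(Am))
  }
  if (is.logical(mask)) mask <- which(mask)
  if (!length(mask)) stop("empty mask", call. = FALSE)
  if (r0 < 1 || r0 > nrow(Am)) stop("`r0` out of range", call. = FALSE)
  tot <- colSums(Am[, mask, drop = FALSE])
  if (any(tot <= 0))
    stop("mask contains pixels with zero total abundance", call. = FALSE)
  mean(Am[r0, mask] / tot)
}

#' Root mean square error between abundance matrices
#'
#' `sqrt(||A - Ahat||_F^2 / (N * R))`.
#'
#' @param A,Ahat matrices of equal shape (R x N).
#' @return non-negative scalar.
#' @export
rmse <- function(A, Ahat) {
  A <- as.matrix(A); Ahat <- as.matrix(Ahat)
  if (!isTRUE(all(dim(A) == dim(Ahat))))
    stop("`A` and `Ahat` must have equal shape", call. = FALSE)
  sqrt(sum((A - Ahat)^2) / length(A))
}

hist_counts <- function(values, bins = 256L) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("degenerate input: need at least 2 distinct values", call. = FALSE)
  lo <- min(values); hi <- max(values)
  bw <- (hi - lo) / bins
  idx <- pmin(pmax(floor((values - lo) / bw), 0), bins - 1L) + 1L
  list(counts = tabulate(idx, bins), lo = lo, bw = bw, bins = bins)
}

#' Otsu threshold (256-bin histogram)
#'
#' Threshold maximizing the between-class variance over a 256-bin histogram
#' of the data range; returns the bin-edge value of the optimal split.
#'
#' @param values numeric sample with at least two distinct values.
#' @param bins number of histogram bins.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  h <- hist_counts(values, bins)
  p <- h$counts / sum(h$counts)
  mids <- h$lo + (seq_len(h$bins) - 0.5) * h$bw
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[h$bins]
  k <- seq_len(h$bins - 1L)
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bcv <- rep(-Inf, h$bins - 1L)
  bcv[valid] <- (mt * w0[k][valid] - m0[k][valid])^2 /
    (w0[k][valid] * w1[valid])
  kbest <- which.max(bcv)
  h$lo + kbest * h$bw
}

#' Triangle threshold (256-bin histogram)
#'
#' Chord construction from the histogram peak to the far end of the longer
#' tail; the threshold is the bin edge with maximal perpendicular distance
#' from the chord.
#'
#' @inheritParams otsu_threshold
#' @return scalar threshold.
#' @export
triangle_threshold <- function(values, bins = 256L) {
  h <- hist_counts(values, bins)
  cnt <- h$counts
  peak <- which.max(cnt)
  nz <- range(which(cnt > 0))
  ## pick the side with the longer tail from the peak
  right <- (nz[2L] - peak) >= (peak - nz[1L])
  end <- if (right) nz[2L] else nz[1L]
  if (end == peak)
    stop("degenerate histogram for triangle threshold", call. = FALSE)
  ks <- if (right) peak:end else end:peak
  ## distance from (k, cnt[k]) to the line (peak, cnt[peak]) -- (end, cnt[end])
  dx <- end - peak
  dy <- cnt[end] - cnt[peak]
  nrm <- sqrt(dx^2 + dy^2)
  d <- abs(dy * (ks - peak) - dx * (cnt[ks] - cnt[peak])) / nrm
  kbest <- ks[which.max(d)]
  h$lo + kbest * h$bw
}

## 8-connected component labelling by flood fill.
label_components <- function(mask) {
  mask <- as.matrix(mask) != 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  offs <- cbind(rep(-1:1, 3L), rep(-1:1, each = 3L))
  offs <- offs[!(offs[, 1L] == 0 & offs[, 2L] == 0), , drop = FALSE]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((i - 1L) %% H) + 1L
      cc <- ((i - 1L) %/% H) + 1L
      nr <- r + offs[, 1L]; ncol_ <- cc + offs[, 2L]
      ok <- nr >= 1L & nr <= H & ncol_ >= 1L & ncol_ <= W
      ni <- (ncol_[ok] - 1L) * H + nr[ok]
      ni <- ni[mask[ni] & lab[ni] == 0L]
      if (length(ni)) {
        lab[ni] <- cur
        stack <- c(stack, ni)
      }
    }
  }
  lab
}

## Marching-squares boundary length of a binary matrix (sub-pixel iso-contour
## at level 0.5). For binary input each boundary 2x2 cell contributes a fixed
## segment length: corner cuts sqrt(2)/2, straight edges 1, saddles sqrt(2).
contour_perimeter <- function(mask) {
  b <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  b[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask != 0)
  H <- nrow(b); W <- ncol(b)
  tl <- b[-H, -W]; tr <- b[-H, -1L]; bl <- b[-1L, -W]; br <- b[-1L, -1L]
  code <- tl + 2L * tr + 4L * bl + 8L * br + 1L
  s2 <- sqrt(2) / 2
  lut <- c(0, s2, s2, 1, s2, 1, 2 * s2, s2, s2, 2 * s2, 1, s2, 1, s2, s2, 0)
  sum(lut[code])
}

#' Circularity of segmented objects
#'
#' Labels 8-connected foreground components and reports, per object, the
#' pixel area, a sub-pixel (marching-squares) boundary-length perimeter, and
#' the circularity `4 * pi * area / perimeter^2`, capped at 1 (small digital
#' objects can otherwise exceed 1, as in common imaging software).
#'
#' @param mask logical or 0/1 matrix.
#' @return data frame with columns `label`, `area`, `perimeter`,
#'   `circularity`; zero rows for an empty mask.
#' @export
circularity <- function(mask) {
  mask <- as.matrix(mask) != 0
  lab <- label_components(mask)
  n <- max(lab)
  out <- data.frame(label = integer(0), area = integer(0),
                    perimeter = numeric(0), circularity = numeric(0))
  for (k in seq_len(n)) {
    obj <- lab == k
    a <- sum(obj)
    p <- contour_perimeter(obj)
    out <- rbind(out, data.frame(
      label = k, area = a, perimeter = p,
      circularity = min(1, 4 * pi * a / p^2)))
  }
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic, Welch-Satterthwaite degrees of freedom and
#' two-sided p-value, computed by the direct formulas.
#'
#' @param x,y numeric samples, each of size >= 2, with nonzero variance in at
#'   least one.
#' @return list with fields `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0)
    stop("both samples have zero variance", call. = FALSE)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
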
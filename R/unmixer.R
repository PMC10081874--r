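## Whole-image unmixing by sliding windows and the reference-image tuning
## procedure.

#' Construct an abundance image
#'
#' @param values non-negative R x H x W array of per-pixel abundances.
#' @param names R endmember labels.
#' @param scale count-rescaling factor already applied to the values (1 if
#'   none); kept so simulated abundances can be mapped back to the original
#'   scale.
#' @return object of class `abundance_image`.
#' @export
abundance_image <- function(values, names = NULL, scale = 1) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be an R x H x W array", call. = FALSE)
  if (any(values < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (is.null(names)) names <- paste0("EM", seq_len(dim(values)[1L]))
  if (length(names) != dim(values)[1L])
    stop("`names` must have one label per endmember", call. = FALSE)
  structure(list(values = values, names = names, scale = scale),
            class = "abundance_image")
}

#' @export
print.abundance_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<abundance_image> R=%d endmembers, %d x %d pixels, scale %.4g\n",
              d[1L], d[2L], d[3L], x$scale))
  invisible(x)
}

#' Unmix a spectral image
#'
#' For `method = "nls"` each pixel is solved independently by non-negative
#' least squares. For the windowed methods every pixel's centred 3x3 window
#' is solved and only the centre column of the window solution is kept, so
#' overlapping windows never mix estimates.
#'
#' @param img a [spectral_image()].
#' @param M an [endmember_matrix()] with `nrow(M)` equal to the channel count.
#' @param method one of `"slpru"`, `"nls"`, `"snls"`, `"slnls"`.
#' @param cfg a [solver_config()]; `lambda1`/`lambda2` are taken from it
#'   (for `"snls"` only `lambda2` is used).
#' @return an [abundance_image()] (scale 1).
#' @export
unmix_image <- function(img, M, method = c("slpru", "nls", "snls", "slnls"),
                        cfg = solver_config()) {
  method <- match.arg(method)
  counts <- if (inherits(img, "spectral_image")) img$counts else img
  M <- as.matrix(M)
  d <- dim(counts)
  if (d[1L] != nrow(M))
    stop("channel mismatch: image has ", d[1L], " channels, M has ",
         nrow(M), " rows", call. = FALSE)
  H <- d[2L]; W <- d[3L]; R <- ncol(M)
  if (method == "nls") {
    Yflat <- matrix(aperm(counts, c(1L, 3L, 2L)), nrow = d[1L])  # row-major pixels
    A <- nnls_cols_cpp(Yflat, M)
  } else {
    cube <- window_cube(counts)
    sol <- switch(method,
      slpru = solve_windows_cpp(cube, M, cfg$lambda1, cfg$lambda2, cfg$mu,
                                cfg$tol, cfg$max_iter, cfg$outer_reweights,
                                cfg$eps_scale, TRUE, TRUE),
      snls  = solve_windows_cpp(cube, M, 0, cfg$lambda2, cfg$mu, cfg$tol,
                                cfg$max_iter, 1L, cfg$eps_scale, FALSE, FALSE),
      slnls = solve_windows_cpp(cube, M, cfg$lambda1, cfg$lambda2, cfg$mu,
                                cfg$tol, cfg$max_iter, 1L, cfg$eps_scale,
                                FALSE, FALSE))
    A <- sol[, 5L, , drop = TRUE]              # centre column per window
    if (is.null(dim(A))) A <- matrix(A, nrow = R)
  }
  ## A columns are in row-major pixel order; refold to R x H x W
  vals <- aperm(array(A, c(R, W, H)), c(1L, 3L, 2L))
  abundance_image(vals, names = colnames(M), scale = 1)
}

## Foreground mask: pixels whose summed-channel count exceeds the Otsu
## threshold AND whose estimated total abundance is positive.
foreground_mask <- function(img, abund) {
  counts <- if (inherits(img, "spectral_image")) img$counts else img
  tot <- apply(counts, c(2L, 3L), sum)
  thr <- tryCatch(otsu_threshold(as.numeric(tot)),
                  error = function(e) -Inf)  # constant image: keep all
  asum <- apply(abund$values, c(2L, 3L), sum)
  tot > thr & asum > 0
}

#' Tune penalty weights on single-fluorophore reference images
#'
#' Every pair on the grid `grid1 x grid2` is scored by unmixing each
#' reference image with the full endmember matrix and computing the average
#' proportion of its (known) endmember over foreground pixels. The winning
#' pair maximizes the minimum average proportion across references; ties are
#' broken by the lexicographically smaller `(lambda1, lambda2)`.
#'
#' `method = "snls"` sweeps `grid2` only (lambda1 fixed at 0) and
#' `method = "nls"` has nothing to tune (single cell).
#'
#' @param refs list of [spectral_image()] references; reference r is assumed
#'   to contain only endmember r.
#' @param M full endmember matrix (one column per reference, same order).
#' @param grid1,grid2 candidate values for lambda1 and lambda2.
#' @param method solver passed to [unmix_image()].
#' @param cfg base [solver_config()].
#' @return list of class `slpru_tuning`: `grid` (data frame lambda1,
#'   lambda2), `per_reference_proportion` (grid x references),
#'   `min_proportion`, `best` (named vector), `method`.
#' @export
tune_on_references <- function(refs, M,
                               grid1 = c(0, 1e-3, 1e-2, 1e-1, 1, 10),
                               grid2 = c(0, 1e-3, 1e-2, 1e-1, 1, 10),
                               method = c("slpru", "snls", "slnls", "nls"),
                               cfg = solver_config()) {
  method <- match.arg(method)
  if (!length(refs)) stop("need at least one reference image", call. = FALSE)
  M <- as.matrix(M)
  if (length(refs) != ncol(M))
    stop("need one reference per endmember column", call. = FALSE)
  pairs <- switch(method,
    nls   = data.frame(lambda1 = 0, lambda2 = 0),
    snls  = data.frame(lambda1 = 0, lambda2 = sort(grid2)),
    expand.grid(lambda2 = sort(grid2), lambda1 = sort(grid1))[, 2:1])
  if (!nrow(pairs)) stop("empty tuning grid", call. = FALSE)
  nref <- length(refs)
  prop <- matrix(NA_real_, nrow(pairs), nref)
  for (g in seq_len(nrow(pairs))) {
    cfg_g <- cfg
    cfg_g$lambda1 <- pairs$lambda1[g]
    cfg_g$lambda2 <- pairs$lambda2[g]
    for (r in seq_len(nref)) {
      ab <- unmix_image(refs[[r]], M, method = method, cfg = cfg_g)
      mask <- foreground_mask(refs[[r]], ab)
      prop[g, r] <- if (any(mask)) average_proportion(ab, r, mask) else NA_real_
    }
  }
  minp <- apply(prop, 1L, min)
  ## ties (within exact equality) broken by lexicographically smaller pair;
  ## pairs are generated in lexicographic order so which.max suffices
  best_i <- which.max(minp)
  structure(list(
    grid = pairs,
    per_reference_proportion = prop,
    min_proportion = minp,
    best = c(lambda1 = pairs$lambda1[best_i], lambda2 = pairs$lambda2[best_i]),
    best_min_proportion = minp[best_i],
    method = method), class = "slpru_tuning")
}

#' @export
print.slpru_tuning <- function(x, ...) {
  cat(sprintf("<slpru_tuning> method=%s, %d grid points, %d references\n",
              x$method, nrow(x$grid), ncol(x$per_reference_proportion)))
  cat(sprintf("  best: lambda1=%g lambda2=%g (min average proportion %.4f)\n",
              x$best["lambda1"], x$best["lambda2"], x$best_min_proportion))
  invisible(x)
}
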
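## Synthetic data: endmember spectra, window abundances, Poisson shot noise,
## reference images, and the full simulation study.

#' Simulation specification
#'
#' Captures the simulated world: a C-channel detector, R candidate
#' endmembers of which `active` are present, shot noise at a given SNR, and
#' a replicate count. The window is fixed at 3x3.
#'
#' @param C number of spectral channels (default 32, matching a 32-anode
#'   spectral detector).
#' @param R number of candidate endmembers (default 13).
#' @param active indices of endmembers with nonzero abundance (default
#'   `c(2, 7)`, the analog of the AF514/RRX uncorrelated pair in the
#'   13-fluorophore panel).
#' @param snr signal-to-noise ratio, > 0 (square root of the mean Poisson
#'   rate over positive-rate entries).
#' @param n_reps number of replicates (default 1000).
#' @param seed integer seed.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(C = 32L, R = 13L, active = c(2L, 7L), snr = 5,
                            n_reps = 1000L, seed = 1L) {
  stopifnot(C >= 2, R >= 1, snr > 0, n_reps >= 1)
  active <- as.integer(active)
  if (any(active < 1L) || any(active > R) || anyDuplicated(active))
    stop("`active` must be distinct indices in 1..R", call. = FALSE)
  structure(list(C = as.integer(C), R = as.integer(R), active = active,
                 snr = snr, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), window_shape = c(3L, 3L)),
            class = "simulation_spec")
}

#' Synthetic endmember spectra
#'
#' Generates R unit-sum, log-normal-shaped (asymmetric, as for real organic
#' dyes) spectral profiles with peak channels spread across the detector and
#' a common full width at half maximum of `width` channels. When `min_cos`
#' is given, the peaks of the designated `pair` are moved together until
#' their cosine similarity reaches `min_cos`, emulating highly correlated
#' fluorophores.
#'
#' @param C number of channels (>= 2).
#' @param R number of endmembers (>= 1).
#' @param width approximate FWHM in channels.
#' @param min_cos optional target cosine similarity for `pair`, in (0, 1).
#' @param pair indices of the correlated pair (default `c(6, 7)`, the
#'   AF555/RRX analog).
#' @return an [endmember_matrix()] with attribute `cosines` (R x R pairwise
#'   cosine table).
#' @export
synth_endmembers <- function(C = 32L, R = 13L, width = 4, min_cos = NULL,
                             pair = c(6L, 7L)) {
  stopifnot(C >= 2, R >= 1, width > 0)
  if (!is.null(min_cos) && (min_cos >= 1 || min_cos <= 0))
    stop("`min_cos` must be in (0, 1)", call. = FALSE)
  peaks <- if (R == 1L) (C + 1) / 2 else seq(3, C - 2, length.out = R)
  profile <- function(p) {
    sdlog <- width / (2.3548 * p)
    f <- stats::dlnorm(seq_len(C), meanlog = log(p) + sdlog^2, sdlog = sdlog)
    f / sum(f)
  }
  build <- function(peaks) {
    M <- vapply(peaks, profile, numeric(C))
    endmember_matrix(M, names = paste0("EM", seq_along(peaks)))
  }
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  M <- build(peaks)
  if (!is.null(min_cos)) {
    if (R < 2L) stop("`min_cos` needs at least two endmembers", call. = FALSE)
    pair <- as.integer(pair)
    for (i in 1:200) {
      if (cosine(M[, pair[1L]], M[, pair[2L]]) >= min_cos) break
      peaks[pair[2L]] <- peaks[pair[1L]] +
        0.85 * (peaks[pair[2L]] - peaks[pair[1L]])
      M <- build(peaks)
    }
    if (cosine(M[, pair[1L]], M[, pair[2L]]) < min_cos)
      stop("could not reach requested `min_cos`", call. = FALSE)
  }
  cos_tab <- crossprod(sweep(M, 2L, sqrt(colSums(M^2)), "/"))
  attr(M, "cosines") <- cos_tab
  attr(M, "peaks") <- peaks
  M
}

#' Simulate window abundances
#'
#' R x 9 matrix with rows in `spec$active` drawn i.i.d. U(0,1) and all
#' other rows exactly zero.
#'
#' @param spec a [simulation_spec()].
#' @param seed optional seed overriding `spec$seed`; `NULL` uses the current
#'   RNG state.
#' @return R x 9 abundance matrix.
#' @export
simulate_window_abundances <- function(spec, seed = spec$seed) {
  draw <- function() {
    A <- matrix(0, spec$R, 9L)
    A[spec$active, ] <- stats::runif(length(spec$active) * 9L)
    A
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Apply Poisson shot noise at a target SNR
#'
#' The SNR convention is `snr = sqrt(mean rate over positive entries)`: the
#' clean intensities X are globally rescaled by
#' `s = snr^2 / mean(X[X > 0])` and counts drawn as `Y ~ Poisson(s * X)`.
#' The factor `s` is returned so downstream estimates can be divided by it
#' to return to the original abundance scale.
#'
#' @param X non-negative matrix with some positive entry.
#' @param snr target SNR, > 0.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return list with `Y` (integer count matrix) and `s` (rescaling factor).
#' @export
apply_poisson_noise <- function(X, snr, seed = NULL) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("`X` must be non-negative", call. = FALSE)
  if (!any(X > 0))
    stop("degenerate input: `X` is all zero", call. = FALSE)
  if (snr <= 0) stop("`snr` must be positive", call. = FALSE)
  s <- snr^2 / mean(X[X > 0])
  draw <- function() matrix(stats::rpois(length(X), s * X), nrow(X), ncol(X))
  Y <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(Y = Y, s = s)
}

#' Run the window-level simulation study
#'
#' Reproduces the simulation design: for each SNR, `n_reps` 3x3 windows are
#' drawn with U(0,1) abundances on the active endmember set, Poisson noise
#' is applied, each method unmixes every window (estimates rescaled by 1/s),
#' and the RMSE against the true abundances is recorded. Per (method, SNR)
#' the penalty grid point minimizing the mean RMSE is selected.
#'
#' @param M endmember matrix (C x R) to simulate from and unmix with.
#' @param spec a [simulation_spec()]; `spec$snr` is ignored in favour of
#'   `snrs`.
#' @param snrs SNR values to simulate.
#' @param methods subset of `c("nls", "snls", "slnls", "slpru")`.
#' @param grid1,grid2 candidate lambda1/lambda2 values (snls uses grid2
#'   only; nls has no grid).
#' @param cfg base [solver_config()].
#' @return data frame with one row per (snr, method): columns `snr`,
#'   `method`, `lambda1`, `lambda2`, `mean_rmse`, `sd_rmse`, `n_reps`.
#'   Attribute `grid_results` holds the full per-grid-point mean RMSEs.
#' @export
run_simulation_study <- function(M, spec = simulation_spec(),
                                 snrs = 2:10,
                                 methods = c("nls", "snls", "slnls", "slpru"),
                                 grid1 = c(0, 1e-3, 1e-2, 1e-1, 1, 10),
                                 grid2 = c(0, 1e-3, 1e-2, 1e-1, 1, 10),
                                 cfg = solver_config()) {
  M <- as.matrix(M)
  stopifnot(ncol(M) == spec$R)
  methods <- match.arg(methods, c("nls", "snls", "slnls", "slpru"),
                       several.ok = TRUE)
  grids <- list(
    nls   = data.frame(lambda1 = 0, lambda2 = 0),
    snls  = data.frame(lambda1 = 0, lambda2 = sort(grid2)),
    slnls = expand.grid(lambda2 = sort(grid2), lambda1 = sort(grid1))[, 2:1],
    slpru = expand.grid(lambda2 = sort(grid2), lambda1 = sort(grid1))[, 2:1])
  out <- NULL
  grid_results <- NULL
  for (si in seq_along(snrs)) {
    snr <- snrs[si]
    ## one reproducible replicate set per SNR, shared by all methods
    reps <- withr::with_seed(spec$seed + 1000L * si, {
      lapply(seq_len(spec$n_reps), function(i) {
        A <- matrix(0, spec$R, 9L)
        A[spec$active, ] <- stats::runif(length(spec$active) * 9L)
        X <- M %*% A
        nz <- apply_poisson_noise(X, snr)
        list(A = A, Y = nz$Y, s = nz$s)
      })
    })
    Yc <- array(0, c(nrow(M), 9L, spec$n_reps))
    for (i in seq_len(spec$n_reps)) Yc[, , i] <- reps[[i]]$Y
    for (method in methods) {
      g <- grids[[method]]
      mean_r <- sd_r <- numeric(nrow(g))
      for (k in seq_len(nrow(g))) {
        sols <- if (method == "nls") {
          nnls_cols_cpp(matrix(Yc, nrow = nrow(M)), M)
        } else {
          solve_windows_cpp(Yc, M, g$lambda1[k], g$lambda2[k], cfg$mu,
                            cfg$tol, cfg$max_iter,
                            if (method == "slpru") cfg$outer_reweights else 1L,
                            cfg$eps_scale, method == "slpru",
                            method == "slpru")
        }
        errs <- vapply(seq_len(spec$n_reps), function(i) {
          Ahat <- if (method == "nls")
            sols[, (i - 1L) * 9L + 1:9, drop = FALSE]
          else sols[, , i]
          rmse(reps[[i]]$A, Ahat / reps[[i]]$s)
        }, numeric(1))
        mean_r[k] <- mean(errs)
        sd_r[k] <- stats::sd(errs)
      }
      kbest <- which.min(mean_r)
      out <- rbind(out, data.frame(
        snr = snr, method = method,
        lambda1 = g$lambda1[kbest], lambda2 = g$lambda2[kbest],
        mean_rmse = mean_r[kbest], sd_rmse = sd_r[kbest],
        n_reps = spec$n_reps))
      grid_results <- rbind(grid_results, cbind(
        data.frame(snr = snr, method = method), g,
        data.frame(mean_rmse = mean_r, sd_rmse = sd_r)))
    }
  }
  rownames(out) <- NULL
  attr(out, "grid_results") <- grid_results
  out
}

#' Simulate a single-fluorophore reference image
#'
#' Random blob foreground covering approximately `fg_fraction` of the
#' pixels; foreground pixel spectra are `a * m` with `a ~ U[0.5, 1]`,
#' background is zero, and Poisson noise is applied at the requested SNR.
#'
#' @param m unit-sum endmember spectrum (length C).
#' @param shape `c(H, W)` image shape.
#' @param fg_fraction target foreground fraction in (0, 1].
#' @param snr shot-noise SNR.
#' @param seed integer seed (`NULL` = current RNG state).
#' @return a [spectral_image()] with attributes `s` (count rescaling
#'   factor), `fg` (logical foreground mask) and `abundance` (true H x W
#'   abundance, original scale).
#' @export
simulate_reference_image <- function(m, shape = c(16L, 16L),
                                     fg_fraction = 0.4, snr = 10,
                                     seed = NULL) {
  m <- as.numeric(m)
  stopifnot(abs(sum(m) - 1) < 1e-8, fg_fraction > 0, fg_fraction <= 1)
  H <- shape[1L]; W <- shape[2L]
  gen <- function() {
    fg <- matrix(fg_fraction >= 1, H, W)
    rad <- max(2L, round(min(H, W) / 6))
    for (tries in 1:200) {
      if (mean(fg) >= fg_fraction) break
      cr <- sample.int(H, 1L); cc <- sample.int(W, 1L)
      dr <- outer(seq_len(H) - cr, rep(1, W))
      dc <- outer(rep(1, H), seq_len(W) - cc)
      fg <- fg | (dr^2 + dc^2 <= rad^2)
    }
    a <- matrix(0, H, W)
    a[fg] <- stats::runif(sum(fg), 0.5, 1)
    X <- outer(m, as.vector(a))          # C x (H*W), column-major pixels
    nz <- apply_poisson_noise(X, snr)
    img <- spectral_image(array(nz$Y, c(length(m), H, W)))
    attr(img, "s") <- nz$s
    attr(img, "fg") <- fg
    attr(img, "abundance") <- a
    img
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
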
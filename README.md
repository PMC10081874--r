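# slpru — sparse and low-rank Poisson regression spectral unmixing

`slpru` unmixes multichannel fluorescence microscopy images recorded under
photon shot noise. It is aimed at spectral imaging workflows — e.g. FISH-
labelled microbial communities imaged on a 32-channel spectral confocal
detector — where up to a dozen fluorophores with heavily overlapping
emission spectra must be separated at low signal-to-noise.

## Model

Counts at channel c and pixel n follow `Y[c,n] ~ Poisson((M A)[c,n])`, with
`M` (C x R) the endmember spectra — one unit-sum column per fluorophore —
and `A` (R x N) the non-negative abundances. The pipeline is two-step:

1. **Endmember extraction**: each single-fluorophore reference image is
   factorized by rank-1 Poisson NMF (generalized Kullback-Leibler
   objective, multiplicative updates).
2. **Abundance estimation (SL-PRU)**: for every pixel, its 3x3 window is
   solved by

   ```
   min_{A >= 0}  1' [MA - Y o log(MA)] 1  +  lambda1 ||A||_{wp,*}  +  lambda2 ||Wq A||_{2,1}
   ```

   a Poisson negative log-likelihood plus a weighted nuclear norm (windows
   are spatially correlated, hence low rank) and a weighted l2,1 norm (few
   fluorophores per window). The solver is a four-block consensus ADMM with
   closed-form proxes and inverse-magnitude iterative reweighting,
   implemented in C++ (RcppArmadillo). Least-squares baselines (NLS, S-NLS,
   SL-NLS) and the reference-image tuning procedure (maximize the minimum
   average proportion over a penalty grid) are included, along with a
   simulation framework, evaluation metrics, TIFF/CSV I/O and a CLI.

See `vignettes/slpru-methods.Rmd` for the full account of the model,
solver, tuning rule, synthetic-data design and numerical choices.

## Worked example

```r
library(slpru)

# A synthetic 13-fluorophore panel on a 32-channel detector, with the
# (6,7) pair forced to cosine >= 0.9 (a highly correlated dye pair).
M <- synth_endmembers(C = 32, R = 13, width = 4, min_cos = 0.9, pair = c(6, 7))

# One 3x3 window: two active fluorophores, U(0,1) abundances, shot noise at SNR 5.
spec <- simulation_spec(C = 32, R = 13, active = c(2, 7), snr = 5, seed = 3)
A_true <- simulate_window_abundances(spec)
noisy  <- apply_poisson_noise(M %*% A_true, snr = 5, seed = 4)

fit <- solve_window_slpru(noisy$Y, M,
                          solver_config(lambda1 = 0.1, lambda2 = 1))
rmse(A_true, fit$A / noisy$s)         # SL-PRU:  0.00963
A_nls <- sapply(1:9, function(j) nls_pixel(noisy$Y[, j], M))
rmse(A_true, A_nls / noisy$s)         # NLS:     0.01794
```

The two printed numbers are root-mean-square errors of the estimated
abundances (on the original U(0,1) scale, after dividing by the photon
rescaling factor `s`): the penalized Poisson solver roughly halves the
error of plain pixelwise non-negative least squares on this window. A full
study over SNRs and the penalty grid:

```r
res <- run_simulation_study(M, simulation_spec(active = c(2, 7), n_reps = 100, seed = 11),
                            snrs = c(2, 5, 10),
                            cfg = solver_config(tol = 1e-4, max_iter = 200))
res[res$method %in% c("nls", "slpru"), c("snr", "method", "mean_rmse")]
#>   snr method mean_rmse
#>     2    nls  0.053176
#>     2  slpru  0.024548
#>     5    nls  0.022764
#>     5  slpru  0.009848
#>    10    nls  0.010918
#>    10  slpru  0.005064
```

SL-PRU's mean RMSE is roughly half of NLS at every SNR, and errors shrink
as the photon budget grows.

## Command line

```sh
slpru extract  --refs refs/ --out spectra.csv
slpru unmix    --image img.tif --spectra spectra.csv --method slpru \
               --lambda1 0.1 --lambda2 1 --out abund.tif
slpru tune     --refs refs/ --spectra spectra.csv --method slpru --out report.csv
slpru simulate --snr 5 --active 2,7 --reps 1000 --seed 17 --out results.csv
slpru metrics  --abund abund.tif --channel AF514 --threshold otsu --out morph.csv
```

(the `slpru` executable is installed at
`system.file("cli", "slpru", package = "slpru")`; all subcommands accept
`--seed`, `--config` (DCF key: value file mirroring the flags) and
`--log-level`.)

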
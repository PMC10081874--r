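Package: slpru
Title: Sparse and Low-Rank Poisson Regression Spectral Unmixing
Version: 0.1.0
Authors@R:
    person("SLPRU", "Maintainers", email = "slpru@example.org",
           role = c("aut", "cre"))
Description: Spectral unmixing of multichannel fluorescence microscopy images
    under photon shot noise. Implements rank-1 Poisson non-negative matrix
    factorization for endmember extraction from single-fluorophore reference
    images, a windowed Poisson regression unmixer with weighted nuclear-norm
    and weighted l2,1 penalties solved by ADMM with iterative reweighting
    (SL-PRU), non-negative least-squares baselines (NLS, S-NLS, SL-NLS), a
    reference-image grid-search tuning procedure, evaluation metrics (average
    proportion, RMSE, Otsu and Triangle thresholds, circularity, Welch's
    t-test), a Poisson-noise simulation framework, multi-page TIFF and CSV
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    optparse,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
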
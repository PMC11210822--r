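Package: cpdm
Title: Change-Point Detection in Multichannel Time Series via Diffusion Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects change points in one- or multi-channel time series by
    embedding past and current Hankel sub-sequence windows with diffusion
    maps and scoring change as the distance between the embedded windows
    (CPD-DM), alongside singular spectrum transformation, Hotelling's T2 and
    k-nearest-neighbour comparison scores. Includes margin-based evaluation
    (precision/recall/F1, label-margin AUC, Rand index of segmentations),
    hyperparameter grid search, synthetic mean-shift and variance-shift
    benchmark generators, noise-robustness sweeps, and signal preprocessing
    (range normalisation, anti-aliased downsampling, sliding-frame FFT
    magnitude features) aimed at contact-free respiration monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
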
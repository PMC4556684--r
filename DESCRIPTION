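Package: afmse
Title: Time-Scale Multiscale Entropy and Stroke Risk Statistics for
    Atrial Fibrillation Holter Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes time-scale-based multiscale entropy (sample entropy of
    coarse-grained, 2 Hz resampled ventricular response interval series) and
    conventional heart-rate-variability measures from 24-hour Holter beat
    annotations in permanent atrial fibrillation, summarises entropy over
    spectral scale bands (MeanEn, SlopeEn), and evaluates the very-low-frequency
    subrange entropy as an ischemic-stroke predictor with C-statistics, Cox
    proportional-hazards models, Nelson-Aalen cumulative incidence and
    cross-validated threshold classification. Includes a synthetic generator of
    AF-like interval series (two-regime 1/f-plus-white spectrum) and
    outcome-coupled cohorts so the full pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    survival,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
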
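Package: dysmetrix
Title: Detection of Oculomotor Dysmetria from Horizontal-Saccade Eye Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and machine-learning pipeline for detecting
    oculomotor dysmetria (hypometric and hypermetric saccades, a hallmark of
    cerebellar ataxia) from binocular horizontal gaze-position time series.
    Provides a synthetic saccade-task simulator, preprocessing (range
    normalization, FIR band-pass filtering, median-filter blink removal,
    relative power spectral density), matched-filter template scoring and
    threshold-based surface area, single-scale irregularity measures (sample
    entropy, local fuzzy entropy, dispersion entropy, fluctuation dispersion
    entropy, Higuchi fractal dimension, Lempel-Ziv complexity), multiscale
    complexity profiles via coarse-graining, left-right eye functional
    connectivity (correlation, nonlinear h2, band coherence, Granger
    causality), non-parametric group statistics (Mann-Whitney U, Hedges' g,
    test-retest reliability), and a PCA plus linear-SVM classifier evaluated
    under stratified cross-validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
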
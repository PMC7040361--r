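Package: nirsdip
Title: Online Prediction of fNIRS Hemodynamics and Initial-Dip Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online multi-step-ahead prediction of functional near-infrared
    spectroscopy (fNIRS) oxy- and deoxyhemoglobin signals using exponentially
    weighted recursive least squares (RLS) and kernel recursive least squares
    (KRLS) with approximate-linear-dependency (ALD) dictionary sparsification,
    together with dual-threshold vector-phase analysis for low-latency
    detection of the initial dip that precedes the main hemodynamic response.
    Includes a three-gamma hemodynamic response model, Butterworth band-pass
    preprocessing, a synthetic finger-tapping data generator for end-to-end
    validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
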
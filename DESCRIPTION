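Package: nirsclench
Title: Rest Versus Tooth-Clench Classification of Prefrontal fNIRS
    Hemoglobin Signals by Grayscale Image Encoding and Convolutional
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating rest from tooth clenching in
    multi-channel prefrontal functional near-infrared spectroscopy
    (fNIRS) hemoglobin recordings. Provides a synthetic cohort
    generator with hemodynamic-response task effects and physiological
    noise, zero-phase low-pass filtering, block-design windowing with
    baseline-referenced deltas and 2-SD artifact masking, encoding of
    per-sample channel deltas into 5x10 grayscale frames (oxy, deoxy,
    and mixed oxy/deoxy layouts), class counterbalancing, subject-grouped
    five-fold cross-validation of an AlexNet-topology convolutional
    network trained from scratch, and an evaluation stack covering
    confusion-matrix identification rates, fold aggregation, pooled ROC
    curves with DeLong confidence intervals, stepwise multiple-proportion
    comparison of networks, and conventional channel-wise paired t-tests
    with Bonferroni adjustment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
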
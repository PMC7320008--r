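Package: fusfc
Title: Resting-State Functional Connectivity and Dynamic Brain States for
    Functional Ultrasound Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state functional connectivity in
    power-Doppler functional ultrasound (fUS) recordings of the rodent brain.
    Provides seed-based correlation maps and ROI-ROI correlation matrices with
    Fisher-z group statistics (normality-gated Welch or exact Mann-Whitney
    tests, Benjamini-Hochberg false-discovery control), phase-based dynamic
    functional connectivity decomposed into recurring brain states by L1
    (cityblock) k-means clustering of instantaneous phase-locking matrices,
    Spearman correlation of connectivity alterations with behavioural
    measures, and composite-biomarker ROC classification with frozen-threshold
    external validation. Includes a Markov state-switching oscillator
    simulator that generates ground-truth-known synthetic cohorts for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
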
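Package: mirvote
Title: Serum miRNA Diagnostic Classifiers by Weighted Voting on qPCR Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for constructing and validating blood-borne
    miRNA diagnostic classifiers from qPCR cycle-threshold (Ct) profiles:
    quality control of Ct matrices with spike-in and percentile filters,
    model-based (NormFinder-style) reference-miRNA selection with bootstrap
    median-rank aggregation, delta-delta-Ct and z-score normalization frozen
    on training parameters, a signal-to-noise weighted-voting classifier with
    repeated stratified k-fold cross-validation for feature-count selection
    and inclusion-frequency feature selection, and diagnostic performance
    evaluation (confusion metrics, ROC/AUC, stratified positivity). Includes
    a synthetic-cohort generator with recorded ground truth so every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
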
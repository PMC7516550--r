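Package: ceemdx
Title: Epileptic Seizure Detection in EEG by Complementary Ensemble
    Empirical Mode Decomposition and Gradient Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects epileptic seizures in single- and multi-channel EEG
    recordings. Segments recordings with a sliding window, decomposes each
    segment into intrinsic mode functions with empirical mode decomposition
    and its ensemble variants (EEMD, and CEEMD with complementary
    positive/negative white-noise pairs), extracts multi-domain features
    (time, frequency, time-frequency, and six entropy estimators) from the
    raw signal and every decomposed component, prunes features by
    gradient-boosting importance score, and evaluates a boosted-tree
    classifier with stratified k-fold cross-validation reporting
    sensitivity, specificity, and accuracy. Includes a synthetic EEG
    generator so the whole pipeline is testable without clinical data,
    readers for plain-text (Bonn-style) segments and EDF recordings, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
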
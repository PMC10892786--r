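Package: somnoboost
Title: Single-Channel EEG Sleep Staging with Swarm-Tuned Gradient Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic sleep-stage classification from a single EEG channel.
    Implements the full analysis chain: EDF signal and hypnogram input with
    R&K-to-AASM stage harmonisation, band-pass preprocessing and nine-sub-band
    decomposition of 30-second epochs, a 52-feature set spanning time,
    frequency and complexity domains, temporal feature shifting to 154
    columns, particle swarm optimisation of gradient-boosted-tree
    hyperparameters, and stratified 10-fold evaluation with Cohen's kappa,
    weighted per-class metrics and one-vs-rest ROC/AUC. A seeded synthetic
    EEG generator with stage-dependent spectral structure makes the whole
    pipeline testable without access to polysomnography archives.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    xgboost,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
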
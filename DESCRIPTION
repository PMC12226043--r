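Package: capflow
Title: Compound Action Potential Detection, Sorting, Firing Analysis and
    Immune-State Decoding for Vagus Nerve Cuff Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for extracellular vagus nerve cuff-electrode
    recordings: band-pass filtering, respiratory-burst detection, adaptive
    threshold spike extraction, t-SNE/DBSCAN spike sorting with ECG-based
    cardiac-cluster rejection, respiratory-burst-aware firing-rate analysis,
    cytokine-response statistics and Gaussian naive Bayes decoding of immune
    state from per-unit firing rates. Includes a seedable synthetic-recording
    generator with ground truth for end-to-end validation, calibrated to the
    group statistics of control and long-sepsis mouse cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    Rtsne,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
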
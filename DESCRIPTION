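Package: diracnet
Title: Differential Rank Conservation Transforms and Rank-Based
    Multi-Network Classifiers for Transcriptomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms within-sample gene orderings over curated gene sets
    (pathways) into binary pairwise-comparison vectors, estimates per-class
    consensus Rank Templates, and scores samples by Rank Matching and Rank
    Difference Scores. Provides a multi-network one-vs-rest linear support
    vector machine classifier built on rank-difference features, together
    with expression-value and within-sample-rank baseline classifiers, a
    double-loop (outer/inner) cross-validation signature-selection procedure
    with an empirical-Bayes moderated-t screen and global-test ranking, a
    synthetic-data generator with subtype-specific pathway rank regulation,
    preprocessing-variant and batch-effect emulators, and an experiment
    runner that quantifies classifier robustness to those perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
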
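Package: nsafvolcano
Title: Label-Free Pull-Down Interactomics by Pseudocounted NSAF and
    Hyperbolic Volcano Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential interactor analysis for label-free AP-MS
    (pull-down) spectral-count data comparing a modified bait against a
    control bait. Implements pseudocounted Normalized Spectral Abundance
    Factor (NSAF) normalization, identification-level filtering
    (minimum matched peptides, unique-peptide requirement, cross-species
    deduplication), per-protein Welch two-sample statistics on replicate
    NSAF values, and interactor classification on the volcano plane with
    a hyperbolic significance threshold curve combined with a
    fold-change gate. Includes a negative-binomial spectral-count
    simulator with known ground truth so the full pipeline is
    exercisable and testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
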
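Package: clinotext
Title: Rule-Based Text Mining of Performance Status and Progression-Free
    Survival from Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A rule-based pipeline for extracting ECOG/WHO performance
    status and progression-free survival from dated free-text oncology
    notes. Provides text normalization tuned to clinical shorthand,
    sentence segmentation for punctuation-poor notes, n-gram and
    keyword-in-context utilities for rule discovery, a configurable
    regular-expression rule engine that labels sentences as before,
    around, or after disease progression, temporal logic that matches a
    baseline performance status to treatment initiation and resolves a
    progression or censoring date per patient, and an evaluation layer
    (class-wise and weighted F1, Kaplan-Meier median with confidence
    interval, Harrell's concordance index, ratio-based discrepancy
    flags). A synthetic cohort generator with known ground truth and
    documented noise modes makes the whole pipeline testable without
    patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
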
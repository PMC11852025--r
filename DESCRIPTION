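Package: surfmark
Title: Surface-Proteome Marker Discovery for Sexed Bovine Spermatozoa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style pipeline that turns label-free surface-proteome
    quantification of unsexed (BU), X-sorted (BX) and Y-sorted (BY) bovine
    spermatozoa into a ranked list of X-sperm-specific, surface-accessible,
    transmembrane candidate markers. Implements MaxQuant protein-groups
    ingestion with decoy/contaminant removal, the valid-value filter and
    detection-limit (downshifted-normal) imputation, empirical-Bayes moderated
    two-group testing with Benjamini-Hochberg control, per-condition detection
    profiles and Venn/exclusive-set partitions, GO-based cell-surface interest
    classification against fourteen fixed plasma-membrane/cell-surface GO
    identifiers, transmembrane-topology parsing (3line and tabular dialects),
    the surface-accessibility rule engine with candidate prioritization,
    generic Fisher-exact overrepresentation testing, affine-gap global
    alignment for cross-species similarity, and a seeded synthetic-data
    generator with a ground-truth ledger so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
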
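Package: stromashift
Title: Chemotherapy-Induced Remodeling of Cancer-Associated Fibroblast
    Populations and Their Spatial Relationship to T Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how chemotherapy reshapes cancer-associated
    fibroblast (CAF) heterogeneity in tumors and how that remodeling
    relates to CD8+ T-cell infiltration. Implements immunohistochemistry
    scoring arithmetic (H-scores, nuclear-localization scores,
    tumor-infiltrating-lymphocyte densities, paired before/after delta
    scores), a quartile-threshold decision tree classifying tumors into
    the CAF-S1..S4 populations, spatial co-occurrence and
    neighborhood-enrichment statistics on segmented cell maps,
    non-negative matrix factorization (plain and consensus) of spot-level
    expression and cell-abundance matrices, gene-set scores with
    expression-matched controls, regulon-based transcription-factor
    activity scores, and exact small-sample inferential tests. A
    synthetic-data generator with known ground truth stands in for
    controlled-access patient material so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    cluster,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
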
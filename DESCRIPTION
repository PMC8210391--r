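Package: exocargo
Title: Sequence-Based Prediction of Exosome Luminal Cargo Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts whether a protein can be secreted as exosome luminal
    cargo from its amino-acid sequence alone. Provides the full workflow:
    FASTA and annotation-table input, five fixed-length sequence encodings
    (amino-acid composition, dipeptide composition, physico-chemical
    property averages and their combinations), global-alignment identity
    statistics and identity-threshold redundancy reduction for dataset
    curation, random-forest training with repeated stratified tenfold
    cross-validation over a tree-count grid, the standard binary
    classification metrics (sensitivity, specificity, accuracy, Matthews
    correlation, ROC AUC), and a gated prediction report that returns NA
    for proteins that are non-vertebrate or carry a signal peptide or
    transmembrane region. A seeded synthetic-data generator with
    controllable compositional signal makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
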
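Package: perDriveR
Title: Personalized Classification of Tumor Suppressor Genes and Oncogenes
    from Multi-Omic Tumor Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Supervised labeling of altered genes in individual tumor
    samples as tumor suppressor (TSG), oncogene (OG), or neutral.
    Combines mutation-impact encodings, single-sample differential
    expression against pooled normals under a common negative-binomial
    dispersion, protein-interaction-network centrality and neighborhood
    fold-change features, gene-level copy-number scores, and oncogenic
    miRNA expression into per (sample, gene) feature tables, and trains
    imbalance-aware ensemble classifiers (balanced bagging, balanced
    random forest, easy ensemble) with sample-level train/test splits,
    grid-search cross-validation, label-permutation and
    network-randomization controls, per-sample driver rankings, and
    consensus feature-importance reports. Ships a synthetic multi-omic
    cohort generator with planted class signal so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    rpart,
    randomForest,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
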
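Package: regionprop
Title: Region-Specific Propagation of Protein Function Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Splits protein sequences into candidate functional regions by
    consensus over typed InterProScan annotations, encodes regions in four
    TF-IDF-weighted feature spaces (k-mers, keywords, InterPro entry IDs,
    member-database signature IDs), and trains a per-GO-term group-instance
    cost function that localizes known protein-level Gene Ontology labels to
    regions via max aggregation, a kernel-smoothness term, sparse known
    region anchors and L2 regularization. Includes region- and protein-level
    evaluation (AUPR, bootstrap, Wilcoxon signed rank, F1-max calling),
    whole-protein and sequence-identity baselines, temporal-holdout label
    assembly from GAF files, and a seeded synthetic-corpus generator so the
    full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    glmnet,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
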
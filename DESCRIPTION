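Package: hblpred
Title: Prediction and Hierarchical Classification of Bacterial
    Hemoglobin-Like Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-based prediction of bacterial hemoglobin-like (HbL)
    proteins with support vector machines. Implements five composition-based
    feature encodings of protein sequences (amino-acid composition, dipeptide
    composition, a fixed abundance-ordered composition profile, their hybrid,
    and a 400-dimensional composition of min-max normalized position-specific
    scoring matrices), an RBF-kernel SVM classification core, and a
    three-stage hierarchical classifier: HbL versus non-HbL, globin subfamily
    (single-domain, flavohemoglobin, truncated hemoglobin), and five-way
    domain-architecture subgroup assignment. Includes dataset curation
    utilities (annotation-keyword filtering, greedy redundancy reduction),
    k-fold cross-validation with confusion-matrix metrics (accuracy,
    sensitivity, specificity, MCC, false positive rate) and ROC/AUC analysis,
    and a seeded synthetic-sequence generator so every training and
    evaluation path is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    e1071,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, SupportVectorMachine, Proteomics, SequenceMatching
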
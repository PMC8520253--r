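Package: comention
Title: Semi-Supervised Classification of Protein-Phenotype Co-Mentions
Version: 0.1.0
Authors@R:
    person("comention", "developers", email = "comention@example.org",
           role = c("aut", "cre"))
Description: A pipeline for sentence-level relation extraction between human
    proteins and Human Phenotype Ontology (HPO) terms. Extracts co-mentions
    of proteins and phenotypes from a document corpus with dictionary
    matching, masks and encodes sentences for neural text classifiers,
    expands a small labeled training set by self-training on a large
    unlabeled pool, and classifies each co-mention as conveying a valid
    ("good") or invalid ("bad") relationship using a probability-averaging
    ensemble of convolutional and recurrent networks. Includes an evaluation
    harness (precision, recall, F1, AUROC, repeated hold-out, paired
    t-tests), a confidence-ranked sentence retrieval engine for curation
    assistance, and a template-based synthetic data generator so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    stringi,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
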
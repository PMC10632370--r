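Package: pucore
Title: Positive-Unlabeled Graph Ensemble Learning for Core Gene Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts core-like disease genes from molecular networks and
    gene-level features using positive-unlabeled (PU) learning. Base
    classifiers (multilayer perceptrons and graph neural network layers:
    GCN, TAG, RGCN, FiLM, plus random-walk network embeddings and LINKX)
    are trained inside a nested cross-validation ensemble. Within each
    outer fold the agreement of the inner models on held-out positive
    genes is compared against a simulated random background to select a
    statistically justified agreement threshold, and per-gene consensus
    scores count how many outer folds select a gene as a candidate.
    Includes integrated-gradients model interpretation for edges and
    node features, enrichment-based external validation statistics
    (Fisher's exact test by consensus-score bin, Tukey HSD group
    comparisons, rank-sum drug-degree tests, two-proportion z-tests,
    Benjamini-Hochberg correction), and a seeded synthetic-data
    generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    igraph,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
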
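Package: ptppi
Title: Protein-Protein Interaction Prediction with Point Transformers on
    Spherical Convex Hull Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts binary protein-protein interactions from protein
    surface geometry and sequence context. Protein chains are converted to
    oriented surface point clouds carrying chemical one-hot features and
    multi-scale mean/Gaussian curvature estimates, turned into sparse
    connected geometric graphs with the hyperparameter-free spherical
    convex hull (SCHull) construction (with radius and k-nearest-neighbour
    baselines), and classified by a Point Transformer network fused with
    pooled protein language-model sequence embeddings. Includes a
    deterministic synthetic dimer generator, training with early stopping,
    cross-validation, ablation switches, and binary classification
    metrics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
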
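Package: embedbench
Title: Benchmarking Distance and Neighborhood Preservation of 2D Single-Cell Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-cell RNA-seq count data with known ground-truth
    classes from a negative binomial model, produces four kinds of 2D embeddings
    (PCA, t-SNE, UMAP, and an adversarial shape-constrained autoencoder that
    forces the data onto an arbitrary contour such as an elephant outline), and
    scores them with two distance-preservation metrics (inter- and intra-class
    correlation) and four neighborhood/class-preservation metrics (kNN accuracy,
    kNN recall, silhouette coefficient, and maximum adjusted mutual information
    over an HDBSCAN hyperparameter sweep), including high-dimensional baselines.
    The benchmark exposes the dissociation between preserving distances and
    preserving neighborhoods or cluster structure in 2D visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    Rtsne,
    uwot,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    readr,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
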
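Package: hgnetnmf
Title: Hypergraph-Regularized Network Non-Negative Matrix Tri-Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint non-negative matrix tri-factorization of two within-modality
    association networks and one cross-modality association network, with
    hypergraph Laplacian regularization on both factor matrices (HG-netNMF).
    Discovers paired feature modules -- for example brain region-of-interest
    modules coupled to gene modules in imaging genetics -- from absolute
    Pearson correlation networks. Includes a latent-factor simulator for
    paired data, k-nearest-neighbour hypergraph construction, multiplicative
    KKT update rules with convergence diagnostics, neighbour-size and
    regularization-weight selection by reconstruction error, z-score module
    membership with small-module filtering, thresholded correlation networks
    with maximal-clique-centrality hub ranking, and RMSE/MAE/AUC utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
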
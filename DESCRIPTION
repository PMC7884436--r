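Package: schae
Title: Hierarchical Autoencoder Analysis of Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses single-cell RNA-seq expression matrices with a
    two-stage hierarchical autoencoder: a one-layer non-negative kernel
    autoencoder scores and filters genes by encoder-weight variance, then a
    stacked Bayesian (variational) autoencoder projects cells into a
    low-dimensional latent space. On that latent space the package performs
    unsupervised cell segregation (k-nearest-neighbour spectral clustering
    with weighted meta-cluster consensus and an optional voting procedure
    for large data), two-dimensional visualization by minimizing the
    Kullback-Leibler divergence between neighbourhood distributions,
    transductive cell-type classification, and non-branching pseudotime
    inference via a minimum spanning tree. Includes a negative-binomial
    simulator with dropout, batch effects and linear trajectories for
    fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
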
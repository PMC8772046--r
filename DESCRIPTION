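Package: tglrr
Title: Truncated Nuclear Norm and Graph-Laplacian Regularized Low-Rank
    Representation for Tumor Clustering and Gene Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Subspace clustering and feature-gene selection for
    gene-expression matrices via low-rank representation.  The model
    decomposes an expression matrix X into a sample-space component X Z, a
    feature-space component G X and a sparse error P, replacing the nuclear
    norm on Z with the truncated nuclear norm (leaving the leading r
    singular values unpenalized) and adding a k-nearest-neighbour
    graph-Laplacian penalty that preserves local manifold structure among
    samples.  The non-convex objective is solved by a linearized
    alternating-direction method with adaptive penalty (LADMAP).  Includes
    K-means clustering on the learned representation, external cluster
    validity indices (accuracy by optimal assignment, normalized mutual
    information, pairwise F-measure), gene ranking from the feature
    component, a union-of-subspaces synthetic data generator, PCA
    preprocessing, delimited-text input/output and a pipeline driver with
    grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
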
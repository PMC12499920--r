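Package: stardust
Title: Iterative Cell-Gene Co-Embedding and Clustering for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Places single cells and their marker genes on one 2D map by
    iteratively building a heterogeneous cell-gene nearest-neighbor network,
    laying it out with a simulated-annealing (OpenOrd-style) force-directed
    layout, clustering the layout with DBSCAN, and rewiring the network with
    differentially expressed genes over four passes. Includes structure
    preserving subsampling for rare-population retention, an
    overestimated-variance t-test marker ranking, post-hoc assignment of
    held-out cells, projection of marker genes onto external embeddings such
    as UMAP, spatial zonation scoring of clusters via Stouffer combination of
    probabilistic gene-to-bin mapping scores, bootstrapped coordinate
    prediction from marker genes, clustering quality metrics, and a
    deterministic synthetic-data generator.
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
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    igraph,
    FNN,
    RcppAnnoy,
    irlba,
    rpart,
    uwot,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    ggrepel,
    jsonlite,
    optparse
Config/testthat/edition: 3
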
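Package: vwclust
Title: Vector-Valued Wasserstein Clustering of Multi-Omics Samples on Gene
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates multiple omics layers (expression, copy number,
    methylation) as vector-valued probability distributions on a gene
    interaction network and compares samples with the vector-valued W1
    (Earth Mover's) distance, solved exactly as a minimum-cost flow on a
    layered super-graph. Per-sample node weights are converted to
    Markov-chain stationary measures on the network, pairwise distances
    are assembled into a matrix, and samples are grouped by agglomerative
    hierarchical clustering. Includes a synthetic-data generator with
    planted cluster structure, TSV/SIF readers and writers, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    parallel,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
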
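Package: coocnet
Title: Co-Occurrence Network Inference for Plankton Metabarcoding Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers significance-thresholded co-occurrence networks from
    taxa-by-sample metabarcoding count tables together with environmental
    parameters. Provides second-level agglomeration of sequence clusters at a
    percent-identity threshold, prevalence filtering and depth-aware log
    normalization, permutation null models that determine dataset-specific
    Spearman rho significance thresholds, persistence-filtered consensus
    networks, graph-topology reports, keystone-node detection by bootstrapped
    betweenness centrality intersected with articulation points, and cascading
    targeted-attack robustness curves. A synthetic-data generator with planted
    co-occurring guilds provides a ground-truth test surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    boot,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
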
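Package: mesocarto
Title: Modular Structure and Meso-Scale Cartography of Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of the modular structure of undirected
    biological networks. Provides greedy modularity (Clauset-Newman-Moore)
    and two-level map-equation (infomap-style) community detection, network
    null models (Erdos-Renyi and degree-preserving rewiring), cluster-size
    and partition-overlap descriptors, Guimera-Amaral Z-P cartography with
    the seven universal node roles, the biological homogeneity index with a
    within-cluster label-shuffle null, and degree-controlled gene-set role
    enrichment (Fisher/BH plus a degree-matched bootstrap), together with
    ROC/AUC comparison of topological predictors (DeLong test) and seeded
    synthetic-network generators with planted two-scale community structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
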
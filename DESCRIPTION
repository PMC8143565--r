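Package: lpamni
Title: Deterministic Community Detection by Modularity-Seeded Label Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects community structure in simple undirected networks with
    LPA-MNI, a deterministic variant of label propagation that first builds
    rough communities by greedy modularity-gain local moving and then runs
    asynchronous label propagation ordered and tie-broken by degree-centrality
    node importance. Also provides the classical stochastic label propagation
    baseline, partition-quality and partition-agreement metrics (modularity,
    normalized and adjusted mutual information, stability entropy), planted
    partition (Girvan-Newman) and LFR-style benchmark generators, and a small
    command-line interface for running detection and stability experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
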
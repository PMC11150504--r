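Package: hypermem
Title: Memory and Cross-Order Correlations in Temporal Hypergraphs
Version: 0.1.0
Authors@R:
    person("hypermem", "developers", email = "hypermem@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify temporal memory in systems with group (higher-order)
    interactions. A temporal hypergraph is represented as a time-indexed sequence
    of hyperedge sets; each order of interaction is projected onto a sequence of
    node-by-node adjacency matrices, from which intra-order and cross-order
    correlation functions, a normalized interaction matrix, and a cross-order gap
    function are estimated. The package also provides discrete autoregressive
    hypergraph models (DARH and its cross-memory extension cDARH) to simulate
    temporal hypergraphs with tunable intra- and cross-order memory, a
    time-shuffling null model, reconstruction of group interactions from pairwise
    contact streams by maximal-clique promotion, and synthetic fixture generators
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
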
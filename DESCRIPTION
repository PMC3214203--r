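Package: geconet
Title: Gene Co-Expression Network Inference, Topology, Null Models, and
    Cluster Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers gene co-expression networks from expression matrices by
    Pearson correlation thresholding, characterizes global and local network
    topology (degree, density, shortest paths, diameter, betweenness,
    clustering coefficients, assortativity, power-law degree-distribution
    fits), compares observed topology against degree-preserving rewiring,
    Erdos-Renyi, and planted modular random-graph null ensembles, detects
    communities by greedy modularity agglomeration, Louvain, Markov
    clustering, and spectral bisection, compares networks by Jaccard index and
    edge-set algebra, and scores cluster-level functional enrichment with
    hypergeometric tests and Benjamini-Hochberg correction. Networks and node
    attributes export to Cytoscape-compatible SIF and attribute tables; a
    synthetic-data module generates expression matrices with planted
    co-expression modules and matched annotations for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
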
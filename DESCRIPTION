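Package: ccmds
Title: Centrality-Corrected Minimum Dominating Sets for Driver-Protein
    Discovery in Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies minimum sets of driver proteins that can control an
    undirected protein-protein interaction network from the dominating-set
    perspective. Implements the standard minimum dominating set (MDS) binary
    integer program and its centrality-corrected extension (CC-MDS), in which
    each protein j carries a weight (d_j * b_j)^(-gamma) built from its degree
    and normalized betweenness centralities, so that the optimizer prefers
    topologically central controllers and the otherwise highly degenerate MDS
    optimum becomes nearly unique. Includes an exact branch-and-bound solver
    with proven optimality, a grid-search procedure that selects the largest
    gamma whose corrected optimum still has minimum cardinality, a greedy
    degree-ranked comparator, and an evaluation battery: Jaccard overlap of
    driver sets, targeted-attack robustness curves, Wilcoxon rank-sum
    centrality comparisons, one-sided Fisher/hypergeometric enrichment tests
    with Bonferroni correction, and per-protein annotation membership counts.
    A synthetic-data module generates the worked toy network, seeded random
    graphs, and annotation sets with planted enrichment for fully reproducible
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
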
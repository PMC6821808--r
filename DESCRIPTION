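Package: riccinet
Title: Ollivier-Ricci Curvature and Robustness Analysis of Brain Structural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Ollivier-Ricci curvature of weighted undirected graphs
    via exact earth mover's distance (Wasserstein-1) linear programming, along
    with classical nodal measures (strength, betweenness centrality, clustering
    coefficient), global network metrics (largest component, global efficiency,
    random-walk entropy rate), targeted node-deletion robustness cascades,
    rank-preserving Gaussian weight transformation, and Holm-Sidak corrected
    two-group comparison of nodal measures across subject cohorts. Includes a
    synthetic connectome generator with exponentially distributed weights and a
    modular block structure, so that every stage of the analysis pipeline can
    be exercised end to end without imaging data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
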
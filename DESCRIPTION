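Package: coloredmotifs
Title: Colored Network Motif Census and Significance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Census and significance analysis of node-colored network motifs
    in mixed directed/undirected graphs such as neuronal wiring diagrams.
    Enumerates induced connected subgraphs of sizes 2-4 with an ESU
    (FANMOD-style) algorithm, assigns each instance to a canonical colored
    isomorphism class, builds color-permutation null ensembles that preserve
    topology and color frequencies, and scores motifs with z-scores, log2
    abundance ratios, permutation P-values and Westfall-Young single-step
    min-P adjusted P-values. Includes a synthetic colored-network generator
    with motif planting for power and calibration studies, and a structural
    taxonomy of 3- and 4-node motifs (chains, feed-forward loops, bi-fans,
    integration/bifurcation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
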
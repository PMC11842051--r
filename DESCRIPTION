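Package: sdblocks
Title: Segmental Duplication Block Decomposition of Genomes via Iterative
    de Bruijn Graph Simplification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes genomes and loci into non-overlapping duplication
    blocks. Inexact repeats are first transformed into exact repeats by
    iteratively building condensed de Bruijn graphs with increasing k-mer
    sizes and collapsing bubbles formed by similar paths; blocks are then
    read off the simplified graph, lifted back to the original coordinates
    by edit-distance alignment, and compared across genomes. Includes a
    gene-window percent-identity analysis for immunoglobulin D genes, block
    plots and scaled block plots, and a planted-duplication simulator with
    truth tracking for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
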
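Package: rinnet
Title: Mining Recurrent Interaction Networks in RNA 2D Structure Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents annotated RNA chains as directed edge-labelled graphs whose
    Leontis-Westhof interaction labels form a proper edge-coloring (PEC), and exploits
    that coloring for fast exact graph matching: graph isomorphism, subgraph
    isomorphism, and enumeration of all maximal connected common subgraphs via a
    constraint-replay backtracking extension core. On top of the matching layer it
    implements a rule system (cycle membership, stack exclusion, basepair requirement,
    long-range interaction thresholds, SSE span) to distill maximal common subgraphs
    into a non-redundant catalog of Recurrent Interaction Networks (RINs) with full
    occurrence bookkeeping, and organises catalogs into inclusion networks. Includes a
    FR3D-style annotation parser, pseudoknot-free secondary structure assignment with
    SSE decomposition, local/long-range interaction classification, a synthetic corpus
    generator with planted motifs, and JSON/DOT export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    igraph,
    ggplot2,
    generics,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
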
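Package: abmotif
Title: Phenotype-Related Conserved Functional Module Discovery in
    Multi-Organism Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate phenotype-related functional modules by
    comparing genome-scale protein functional association networks across
    many organisms. Per-organism networks projected onto clusters of
    orthologous groups (COGs) are combined into a single two-typed, divided
    network whose maximal cliques correspond to modules conserved across
    organisms; a bounded Bron-Kerbosch search enumerates exactly those
    maximal cliques present in at least alpha phenotype-expressing and at
    most beta non-expressing organisms. Includes hypergeometric selection
    of significant (alpha, beta) parameter pairs and per-module phenotype
    bias, a phylogenetic diversity score computed from an organism distance
    matrix, a seeded synthetic-cohort generator with planted modules for
    end-to-end validation, edge-threshold selection against a validation
    COG set, and a subsampling robustness check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
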
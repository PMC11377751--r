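Package: gmscout
Title: Remote-Homology Discovery of Genome-Maintenance Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable reimplementation of a candidate-discovery
    pipeline for genome-maintenance (GM) protein domains. Candidate proteins are
    compiled from Gene Ontology annotation (with child-term propagation), from
    protein-protein interaction tables (DDR/non-DDR pair asymmetry, experimental
    evidence and publication-count filters, housekeeping and contaminant
    exclusion), and from tissue co-expression modules (within-module pairs
    recurring in at least two tissues). Query sequences are masked for coiled-coil
    heptad repeats and low compositional complexity; the unmasked regions seed
    iteratively built multiple sequence alignments, profile hidden Markov models,
    forward profile-to-profile searches against a family library, and reciprocal
    validation with Gumbel-calibrated E-values. A synthetic-data module plants
    homologous domain families at controlled divergence inside decoy proteins,
    together with interaction tables, GO annotation and correlated expression
    modules, so every stage of the pipeline can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    igraph,
    ape,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
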
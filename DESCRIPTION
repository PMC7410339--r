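Package: cutsets
Title: Minimal Cut Sets for Metabolic Network and Strain Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computation of (constrained) minimal cut sets in constraint-based
    metabolic models: minimal sets of reaction or gene deletions and additions
    that make every flux vector in one or more target (undesired) flux regions
    infeasible while keeping every desired region feasible. Implements the
    Farkas-duality mixed-integer formulation with multiple target and desired
    regions, weighted intervention costs and reaction additions; integration
    of gene-protein-reaction (GPR) rules via enzyme-pool pseudo-metabolites
    that preserves original flux ranges; lossless compression of GPR rules and
    of the network (blocked reactions, conservation relations, lumping of
    coupled reactions); and decompression of solutions back to reaction and
    gene level. Includes flux variability analysis, an exhaustive LP-probe
    oracle for validation, tabular and SBML (Level 3 fbc) model input, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
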
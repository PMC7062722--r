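Package: edgetic
Title: Edgetic Perturbation Analysis of Condition-Specific Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds paired condition-specific protein-protein interaction
    networks from transcript-level expression at isoform and domain
    resolution, derives per-patient and per-cohort edge perturbation
    profiles (gained, lost and kept edge codes), scores and ranks rewired
    nodes, tests association of perturbations with significantly mutated
    genes and paired network-size shifts, clusters cohorts by perturbation
    signatures with multiscale bootstrap support values, provides
    degree-preserving network randomization for null models, and simulates
    multi-cohort transcript expression with planted perturbation events
    and full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
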
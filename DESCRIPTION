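Package: assemblage
Title: Null Models of Ecological Assembly for Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for quantifying the ecological processes that assemble
    host-associated microbial communities from OTU count tables, phylogenies,
    taxonomy and genome-function profiles. Implements Hill-number dissimilarity
    curves with constrained-randomization null expectations, phylogenetic
    beta-null deviation based on Generalized UniFrac, quantitative process
    estimates (beta-nearest-taxon index and abundance-weighted Raup-Crick with
    five-way process classification), the competitive lottery model of
    clade-level winner dynamics, a phylogenetic recruitment model that
    estimates the dispersion of taxon arrival order, taxa-function robustness
    (attenuation and buffering under simulated perturbation, with gene
    distribution features), and BVSTEP subset selection. A synthetic-community
    simulator with known assembly regimes, planted lottery clades, known
    recruitment dispersion and tunable functional redundancy makes every stage
    testable by parameter and process recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    vegan,
    biomformat,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr,
    knitr
Config/testthat/edition: 3
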
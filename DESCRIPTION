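Package: crossblup
Title: Genomic Prediction for Crossbred Pigs with Single-Step GBLUP and
    Multi-Trait Animal Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating phenotyping and genotyping
    strategies in three-way crossbreeding programs for pig meat quality and
    carcass composition.  Builds pedigree (A), genomic (G) and blended
    single-step (H) relationship matrices with multi-population allele
    frequencies, fits single- and multi-trait animal models by dense
    mixed-model equations, estimates (co)variance components with a Gibbs
    sampler (compiled core), and runs pedigree-clustered cross-validation
    across phenotyping scenarios (single-trait, purebred indicator and
    crossbred indicator sets) crossed with genotyping stages.  A synthetic
    population generator emulates the paternal half-sib, three-way cross
    structure so every analysis can be exercised without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Matrix,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
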
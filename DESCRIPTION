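Package: defmate
Title: Agent-Based Simulation of Plant Defense and Mating-System Coevolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based forward simulation of the joint evolution of
    herbivory defense (gene-for-gene resistance and inducible tolerance) and
    mating system (heritable or non-heritable selfing) in plant populations
    coevolving with a dioecious herbivore. Fitness combines resistance,
    tolerance and herbivory costs and benefits with two components of
    inbreeding depression (dominance via lethal recessives on a 100-gene load
    genome, and overdominance via individual heterozygosity), under either a
    multiplicative or an additive allocation model with a continuously
    scalable non-linearity exponent. Includes closed-form theory companions
    (scenario fitness maxima, optimal tolerance investment, curvature
    classification, mutation-load equilibria, fitness-surface grids),
    replicate sweeps, persistence summaries and outcome classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
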
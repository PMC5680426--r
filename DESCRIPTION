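Package: phylotox
Title: Phylogenetic Signal and Dose-Response Analysis of Chloride Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-scale evolutionary ecotoxicology toolkit for acute chloride
    (road salt) toxicity. At the macroevolutionary scale it tests for
    phylogenetic signal in species-level chloride LC50 values on a phylogeny
    with Grafen branch lengths, using maximum-likelihood Pagel's lambda with a
    likelihood-ratio test, Blomberg's K with a permutation test, and a Mantel
    matrix-correlation test, including clade-pruned subanalyses. At the
    population scale it fits binomial dose-response models to acute-exposure
    mortality data: a logit-link GLM fitted by iteratively reweighted least
    squares with delta-method LC50 confidence intervals, and a logit-binomial
    mixed model with pond-level and observation-level random intercepts fitted
    by Laplace-approximate maximum likelihood. Seeded generators simulate
    Brownian-motion traits on Yule trees and binomial mortality under the
    ten-pond acute-exposure design, so every stage is verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lme4,
    phytools,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
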
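Package: germfilter
Title: Germination Trait Filtering Along Nitrogen-Addition Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for trait-based analysis of seed germination strategies
    along experimental nitrogen-addition gradients in alpine meadows.
    Computes species-level germination indices (germination percentage and
    rate, responses to alternating temperature and wet-cold storage, and
    temperature-niche occupation, proportion and breadth), a fertilization
    response index from quadrat abundances, community-weighted trait means,
    and the functional diversity indices FRic, FEve and FDiv over a shared
    germination-trait space.  Inference includes beta regression fitted by
    maximum likelihood, Gaussian linear mixed models with a block random
    intercept fitted by profiled maximum likelihood with likelihood-ratio
    tests and Tukey comparisons, and correlation-matrix principal component
    analysis.  A seeded synthetic-data generator emulates the germination
    trials and vegetation quadrats of a factorial nitrogen-addition study so
    every inferential stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
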
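Package: IGEvar
Title: Indirect Genetic Effects on Phenotypic Variability: Simulation and
    Mixed-Model Estimation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates family-structured populations in which competition
    between social partners (an indirect genetic effect on the regression of
    growth on the within-pair body-weight difference) generates inherited
    variability of body weight, and estimates the underlying genetic effects
    with four REML mixed models: direct and indirect sire models on the
    log within-family variance, and direct and indirect sire-dam models on
    the trait itself. Reports Pearson correlations between predicted random
    effects and the simulated breeding values across a canonical grid of
    competition, neutral and cooperation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Genetics, GeneticVariability, StatisticalMethod
RoxygenNote: 7.3.3
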
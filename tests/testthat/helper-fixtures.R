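# Small scenario and hand-built populations used across test files.

tinyScenario <- function(...) {
    GrowthScenario(nSires = 4L, nDamsPerSire = 3L, nOffspringPerDam = 8L, ...)
}

reducedScenario <- function(id, purpose = "variability") {
    applyScale(canonicalScenarios(purpose, ids = id)[[1]], "reduced")
}

# A parent list with chosen breeding values, in the layout produced by
# sampleBasePopulation(): nDamsPerSire dams allocated per sire.
handParents <- function(scenario, sireBV, damBV) {
    nS <- nrow(sireBV)
    nD <- nrow(damBV)
    list(sires = data.frame(id = paste0("S", seq_len(nS)), sireBV),
         dams = data.frame(id = paste0("D", seq_len(nD)), damBV,
                           sire = rep(seq_len(nS),
                                      each = nD / nS)),
         scenario = scenario)
}

bvFrame <- function(A_GR, A_D, A_I) {
    data.frame(A_GR = A_GR, A_D = A_D, A_I = A_I)
}

# Deterministic scenario: every random effect has zero variance.
pointMassScenario <- function(bBar = 0, ...) {
    GrowthScenario(bBar = bBar, sigmaAD = 0, sigmaAI = 0, sigmaED = 0,
                   sigmaEI = 0, sigmaAGR = 0, h2 = 1, repeatability = 1, ...)
}

# Balanced one-way ANOVA estimators: the closed-form oracle for the sire
# model (interior solution).
anovaOneWay <- function(y, g) {
    means <- tapply(y, g, mean)
    n <- length(y) / length(means)
    msw <- sum((y - means[as.character(g)])^2) /
        (length(y) - length(means))
    msb <- n * sum((means - mean(y))^2) / (length(means) - 1)
    list(msw = msw, msb = msb, sigma2e = msw, sigma2s = (msb - msw) / n)
}
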
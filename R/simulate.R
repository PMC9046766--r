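#' @importFrom SummarizedExperiment SummarizedExperiment colData assay
#'   assay<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# Deterministic sub-stream seeds: one master seed per replicate, mixed with a
# stage code so base population, offspring, pairing and growth noise are
# independently reproducible. Arithmetic in doubles (exact below 2^53),
# result in [0, 2^31-2].
.STAGES <- c(base = 1, offspring = 2, pairing = 3, growth = 4, replicate = 5)

#' Derive a stage- and replicate-specific seed from a master seed
#'
#' @param master integer master seed.
#' @param stage one of \code{"base"}, \code{"offspring"}, \code{"pairing"},
#'   \code{"growth"}, \code{"replicate"}.
#' @param replicate replicate index (1-based).
#' @return An integer seed in [0, 2^31 - 2], a deterministic function of the
#'   arguments.
#' @export
deriveSeed <- function(master, stage = "replicate", replicate = 1L) {
    code <- .STAGES[[match.arg(stage, names(.STAGES))]]
    m <- 2147483647  # 2^31 - 1, prime
    x <- (abs(as.numeric(master)) %% m)
    x <- (x * 48271 + code * 1013904223 + as.numeric(replicate) * 69621) %% m
    # one more multiplicative round decorrelates consecutive masters
    as.integer((x * 16807 + 2147480707) %% m)
}

# Factor a covariance matrix Sigma = D C D (D = diag of SDs) as t(L) %*% L
# via symmetric eigendecomposition; tolerates PSD-singular C (e.g. all
# pairwise correlations -0.5) where chol() would fail.
.covFactor <- function(sds, corr) {
    Sigma <- outer(sds, sds) * corr
    e <- eigen(Sigma, symmetric = TRUE)
    vals <- e$values
    if (min(vals) < -1e-8 * max(abs(vals), 1))
        stop("covariance matrix is not positive semi-definite")
    vals[vals < 0] <- 0
    diag(sqrt(vals), length(vals)) %*% t(e$vectors)  # L: Sigma = t(L) L
}

# n x 3 draw of (A_GR, A_D, A_I) with the scenario's SDs and correlations
.drawTriples <- function(n, sds, corr) {
    L <- .covFactor(sds, corr)
    out <- matrix(rnorm(3L * n), nrow = n, ncol = 3L) %*% L
    colnames(out) <- c("A_GR", "A_D", "A_I")
    out
}

#' Sample an unrelated base population of sires and dams
#'
#' Every parent receives a breeding-value triple (growth \code{A_GR},
#' resistance \code{A_D}, cooperativeness \code{A_I}) drawn i.i.d. from the
#' trivariate normal with the scenario's genetic SDs and correlation matrix.
#' Dams are then allocated to sires at random, \code{nDamsPerSire} dams per
#' sire, each dam mated once.
#'
#' @param scenario a \linkS4class{GrowthScenario}.
#' @param seed integer seed for this stage.
#' @return A list with \code{sires} and \code{dams} data.frames (columns
#'   \code{id}, \code{A_GR}, \code{A_D}, \code{A_I}; dams also carry
#'   \code{sire}, the 1-based index of their mate) and the scenario.
#' @examples
#' pp <- sampleBasePopulation(GrowthScenario(nSires = 4, nDamsPerSire = 3), 1)
#' table(pp$dams$sire)
#' @export
sampleBasePopulation <- function(scenario, seed) {
    stopifnot(is(scenario, "GrowthScenario"))
    validObject(scenario)
    set.seed(as.integer(seed))
    nS <- scenario@nSires
    nD <- nS * scenario@nDamsPerSire
    sds <- c(scenario@sigmaAGR, scenario@sigmaAD, scenario@sigmaAI)
    sireBV <- .drawTriples(nS, sds, scenario@geneticCorr)
    damBV <- .drawTriples(nD, sds, scenario@geneticCorr)
    # random allocation: a permutation of dams cut into blocks of
    # nDamsPerSire, one block per sire
    damSire <- integer(nD)
    damSire[sample.int(nD)] <- rep(seq_len(nS), each = scenario@nDamsPerSire)
    list(sires = data.frame(id = paste0("S", seq_len(nS)), sireBV),
         dams = data.frame(id = paste0("D", seq_len(nD)), damBV,
                           sire = damSire),
         scenario = scenario)
}

#' Sample an offspring cohort from a mated base population
#'
#' Each dam produces \code{nOffspringPerDam} offspring. An offspring's
#' breeding-value triple is the sire-dam midparent mean plus a Mendelian
#' sampling deviate with half the additive (co)variance of each trait; the
#' Mendelian covariance matrix is \eqn{\tfrac12 \Sigma_A} with the same
#' correlation structure as the parents. Each offspring also receives a
#' permanent environmental effect on growth (\code{Ep}, SD
#' \eqn{\sigma_{Ep}}) and direct/indirect environmental effects on \eqn{b}
#' (\code{E_D}, \code{E_I}), all drawn once per individual and mutually
#' independent.
#'
#' @param parents output of [sampleBasePopulation()].
#' @param seed integer seed for this stage.
#' @return A \linkS4class{GrowthCohort}; the weight assay is \code{NA} until
#'   [simulateGrowth()] runs and \code{partner} is \code{NA} until
#'   [pairIndividuals()] runs.
#' @export
sampleOffspring <- function(parents, seed) {
    scenario <- parents$scenario
    stopifnot(is(scenario, "GrowthScenario"))
    if (any(parents$dams$sire < 1L) || anyNA(parents$dams$sire))
        stop("every dam must be allocated to a sire")
    set.seed(as.integer(seed))
    k <- scenario@nOffspringPerDam
    nD <- nrow(parents$dams)
    n <- nD * k
    dam <- rep.int(seq_len(nD), rep.int(k, nD))
    sire <- parents$dams$sire[dam]
    sireBV <- as.matrix(parents$sires[c("A_GR", "A_D", "A_I")])
    damBV <- as.matrix(parents$dams[c("A_GR", "A_D", "A_I")])
    mid <- 0.5 * (sireBV[sire, , drop = FALSE] + damBV[dam, , drop = FALSE])
    sds <- c(scenario@sigmaAGR, scenario@sigmaAD, scenario@sigmaAI)
    mend <- .drawTriples(n, sds * sqrt(0.5), scenario@geneticCorr)
    bv <- mid + mend
    dv <- deriveVariances(scenario)
    cd <- DataFrame(
        sire = sire, dam = dam, partner = rep(NA_integer_, n),
        A_GR = bv[, 1L], A_D = bv[, 2L], A_I = bv[, 3L],
        Ep = rnorm(n, 0, sqrt(dv[["sigma_Ep2"]])),
        E_D = rnorm(n, 0, scenario@sigmaED),
        E_I = rnorm(n, 0, scenario@sigmaEI))
    rownames(cd) <- paste0("O", seq_len(n))
    W <- matrix(NA_real_, nrow = scenario@nSteps + 1L, ncol = n,
                dimnames = list(paste0("t", 0:scenario@nSteps), rownames(cd)))
    se <- SummarizedExperiment(assays = list(weight = W), colData = cd)
    metadata(se) <- list(scenario = scenario, parents = parents,
                         seeds = list(offspring = as.integer(seed)),
                         nNegativeWeights = NA_integer_)
    new("GrowthCohort", se)
}

#' Sample a uniform random perfect matching
#'
#' @param n even number of individuals.
#' @param seed integer seed.
#' @return Integer vector \code{p} with \code{p[p[i]] == i} and
#'   \code{p[i] != i} for all \code{i} (a fixed-point-free involution),
#'   uniform over all perfect matchings of \code{n} elements.
#' @export
samplePartnerMap <- function(n, seed = NULL) {
    if (n %% 2L != 0L)
        stop("cohort size must be even to form groups of two")
    if (!is.null(seed)) set.seed(as.integer(seed))
    ord <- sample.int(n)
    partner <- integer(n)
    odd <- ord[seq(1L, n, by = 2L)]
    even <- ord[seq(2L, n, by = 2L)]
    partner[odd] <- even
    partner[even] <- odd
    partner
}

#' Assign social partners within a cohort
#'
#' Creates groups of two by assigning every offspring a social partner drawn
#' uniformly at random from the whole cohort (a uniform perfect matching;
#' full sibs may be paired). The group count is half the cohort size.
#'
#' @param cohort a \linkS4class{GrowthCohort}.
#' @param seed integer seed for this stage.
#' @return The cohort with \code{colData(cohort)$partner} filled.
#' @export
pairIndividuals <- function(cohort, seed) {
    stopifnot(is(cohort, "GrowthCohort"))
    n <- ncol(cohort)
    colData(cohort)$partner <- samplePartnerMap(n, seed)
    md <- metadata(cohort)
    md$seeds$pairing <- as.integer(seed)
    metadata(cohort) <- md
    cohort
}

#' Interaction coefficient of an ordered pair
#'
#' The regression of focal individual \eqn{i}'s growth increment on the
#' body-weight difference with its partner \eqn{j}:
#' \deqn{b_{ij} = \bar b + A_{D,i} + E_{D,i} + A_{I,j} + E_{I,j}.}
#' All components are fixed for life, so \eqn{b_{ij}} is constant over time;
#' it is not symmetric (\eqn{b_{ij} \neq b_{ji}} in general).
#'
#' @param bBar mean interaction coefficient.
#' @param AD,ED direct genetic and environmental effects of the focal
#'   individual (vectorized).
#' @param AI,EI indirect genetic and environmental effects of the partner.
#' @return Numeric vector of coefficients.
#' @examples
#' interactionCoefficient(-0.05, AD = 0.015, ED = 0, AI = -0.015, EI = 0)
#' @export
interactionCoefficient <- function(bBar, AD, ED, AI, EI) {
    bBar + AD + ED + AI + EI
}

#' Simulate paired growth trajectories
#'
#' Iterates the growth recursion over \code{nSteps} time increments: the
#' weight gain of focal individual \eqn{i} between \eqn{t-1} and \eqn{t} is
#' \deqn{\mu_{GR} + A_{GR,i} + E_{p,i} + E_{t,i} +
#'       b_{ij}\,(P_{t-1,j} - P_{t-1,i}),}
#' with \eqn{j} the social partner of \eqn{i}. Both members of a pair are
#' updated synchronously from the weights at \eqn{t-1}. The temporary
#' environmental effect \eqn{E_{t,i}} is redrawn independently at every time
#' step (variance \eqn{\sigma^2_{Et}}); all other effects are fixed for
#' life. Weights are not clamped at zero; the count of negative weights ever
#' observed is stored as a diagnostic in
#' \code{metadata(cohort)$nNegativeWeights} (zero for the canonical
#' parameterizations).
#'
#' @param cohort a paired \linkS4class{GrowthCohort}.
#' @param seed integer seed for the temporary environmental noise.
#' @return The cohort with the \code{"weight"} assay filled: rows are time
#'   points 0..nSteps, columns individuals.
#' @export
simulateGrowth <- function(cohort, seed) {
    stopifnot(is(cohort, "GrowthCohort"))
    cd <- colData(cohort)
    if (anyNA(cd$partner))
        stop("cohort must be paired before growth simulation")
    scenario <- metadata(cohort)$scenario
    set.seed(as.integer(seed))
    n <- ncol(cohort)
    dv <- deriveVariances(scenario)
    sdEt <- sqrt(dv[["sigma_Et2"]])
    b <- interactionCoefficient(scenario@bBar, cd$A_D, cd$E_D,
                                cd$A_I[cd$partner], cd$E_I[cd$partner])
    base <- scenario@muGR + cd$A_GR + cd$Ep
    W <- matrix(NA_real_, nrow = scenario@nSteps + 1L, ncol = n,
                dimnames = dimnames(assay(cohort, "weight")))
    w <- rep.int(scenario@startWeight, n)
    W[1L, ] <- w
    nNeg <- 0L
    for (t in seq_len(scenario@nSteps)) {
        w <- w + base + rnorm(n, 0, sdEt) + b * (w[cd$partner] - w)
        nNeg <- nNeg + sum(w < 0)
        W[t + 1L, ] <- w
    }
    assay(cohort, "weight") <- W
    md <- metadata(cohort)
    md$seeds$growth <- as.integer(seed)
    md$nNegativeWeights <- nNeg
    metadata(cohort) <- md
    cohort
}

#' Simulate a complete cohort for one scenario
#'
#' Runs the four simulation stages (base population, offspring sampling,
#' pairing, growth) with stage seeds derived deterministically from one
#' master seed via [deriveSeed()], so each stage is independently
#' reproducible and identical seeds yield bit-identical cohorts.
#'
#' @param scenario a \linkS4class{GrowthScenario}.
#' @param seed integer master seed for this replicate.
#' @param replicate replicate index used in seed derivation.
#' @return A fully simulated \linkS4class{GrowthCohort}.
#' @examples
#' sc <- GrowthScenario(nSires = 4L, nDamsPerSire = 3L, nOffspringPerDam = 4L)
#' cohort <- simulateCohort(sc, seed = 7)
#' finalWeight(cohort)[1:4]
#' @export
simulateCohort <- function(scenario, seed, replicate = 1L) {
    parents <- sampleBasePopulation(
        scenario, deriveSeed(seed, "base", replicate))
    cohort <- sampleOffspring(parents, deriveSeed(seed, "offspring", replicate))
    cohort <- pairIndividuals(cohort, deriveSeed(seed, "pairing", replicate))
    cohort <- simulateGrowth(cohort, deriveSeed(seed, "growth", replicate))
    md <- metadata(cohort)
    md$seeds$master <- as.integer(seed)
    md$seeds$base <- deriveSeed(seed, "base", replicate)
    metadata(cohort) <- md
    cohort
}

#' Final body weight of each offspring
#'
#' @param cohort a simulated \linkS4class{GrowthCohort}.
#' @return Named numeric vector: the last row of the weight assay (the trait
#'   of interest, e.g. harvest weight).
#' @export
finalWeight <- function(cohort) {
    stopifnot(is(cohort, "GrowthCohort"))
    W <- assay(cohort, "weight")
    W[nrow(W), ]
}

#' Partner map of a paired cohort
#'
#' @param cohort a \linkS4class{GrowthCohort}.
#' @return Integer vector of partner indices (a fixed-point-free involution).
#' @export
partnerMap <- function(cohort) {
    stopifnot(is(cohort, "GrowthCohort"))
    colData(cohort)$partner
}

#' Parent tables of a cohort
#'
#' @param cohort a \linkS4class{GrowthCohort}.
#' @return The list stored by [sampleBasePopulation()]: \code{sires} and
#'   \code{dams} data.frames with their simulated breeding values.
#' @export
parentTable <- function(cohort) {
    stopifnot(is(cohort, "GrowthCohort"))
    metadata(cohort)$parents
}
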
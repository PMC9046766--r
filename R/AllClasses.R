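#' @import methods
#' @importFrom stats rnorm optimize var sd setNames
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Scenario definition for a paired-growth simulation
#'
#' A \code{GrowthScenario} bundles every parameter needed to simulate one
#' population: the growth model parameters (mean growth rate, starting weight,
#' genetic and environmental standard deviations, heritability, repeatability,
#' number of growth increments), the decomposition of the social interaction
#' coefficient \eqn{b} into direct and indirect genetic and environmental
#' components, the genetic correlation structure among the three breeding
#' values (growth \eqn{A_{GR}}, resistance \eqn{A_D}, cooperativeness
#' \eqn{A_I}), and the mating design (number of sires, dams per sire,
#' offspring per dam).
#'
#' @slot scenarioId integer; 1-21 for the canonical grid, \code{NA} for custom
#'   scenarios.
#' @slot label character; \code{"competition"}, \code{"neutral"} or
#'   \code{"cooperation"}, the sign of \code{bBar}.
#' @slot purpose character; \code{"variability"} (100 offspring per dam,
#'   family-variance analyses) or \code{"trait"} (10 offspring per dam,
#'   individual-trait analyses).
#' @slot muGR numeric; mean growth rate per time step (g).
#' @slot startWeight numeric; body weight at time 0 (g).
#' @slot sigmaAGR numeric; genetic SD of growth rate (g).
#' @slot bBar numeric; mean interaction coefficient (negative = competition).
#' @slot sigmaAD,sigmaAI numeric; genetic SDs of the direct and indirect
#'   effects on \eqn{b}.
#' @slot sigmaED,sigmaEI numeric; environmental SDs of the direct and indirect
#'   effects on \eqn{b}.
#' @slot h2 numeric in (0, 1]; heritability of growth rate at \eqn{b = 0}.
#' @slot repeatability numeric; repeatability of growth rate, at least
#'   \code{h2}.
#' @slot nSteps integer; number of growth increments.
#' @slot geneticCorr 3x3 correlation matrix over (A_GR, A_D, A_I).
#' @slot nSires,nDamsPerSire,nOffspringPerDam integer design sizes.
#'
#' @seealso [GrowthScenario()] for the user-facing constructor,
#'   [canonicalScenarios()] for the 21-scenario grid,
#'   [deriveVariances()] for the phenotypic-variance budget.
#' @export
setClass("GrowthScenario",
    representation(
        scenarioId = "integer",
        label = "character",
        purpose = "character",
        muGR = "numeric",
        startWeight = "numeric",
        sigmaAGR = "numeric",
        bBar = "numeric",
        sigmaAD = "numeric",
        sigmaAI = "numeric",
        sigmaED = "numeric",
        sigmaEI = "numeric",
        h2 = "numeric",
        repeatability = "numeric",
        nSteps = "integer",
        geneticCorr = "matrix",
        nSires = "integer",
        nDamsPerSire = "integer",
        nOffspringPerDam = "integer"
    )
)

setValidity("GrowthScenario", function(object) {
    msg <- character()
    sds <- c(sigmaAGR = object@sigmaAGR, sigmaAD = object@sigmaAD,
             sigmaAI = object@sigmaAI, sigmaED = object@sigmaED,
             sigmaEI = object@sigmaEI)
    if (any(!is.finite(sds)) || any(sds < 0))
        msg <- c(msg, "all standard deviations must be finite and >= 0")
    if (!is.finite(object@h2) || object@h2 <= 0 || object@h2 > 1)
        msg <- c(msg, "h2 must lie in (0, 1]")
    if (object@repeatability < object@h2 || object@repeatability > 1)
        msg <- c(msg, "repeatability must lie in [h2, 1]")
    if (object@nSteps < 1L)
        msg <- c(msg, "nSteps must be >= 1")
    if (!object@purpose %in% c("variability", "trait"))
        msg <- c(msg, "purpose must be 'variability' or 'trait'")
    C <- object@geneticCorr
    if (!is.matrix(C) || any(dim(C) != 3L)) {
        msg <- c(msg, "geneticCorr must be a 3x3 matrix")
    } else {
        if (max(abs(C - t(C))) > 1e-10)
            msg <- c(msg, "geneticCorr must be symmetric")
        if (max(abs(diag(C) - 1)) > 1e-10)
            msg <- c(msg, "geneticCorr must have unit diagonal")
        ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-8)
            msg <- c(msg, "geneticCorr must be positive semi-definite")
    }
    if (object@nSires < 1L || object@nDamsPerSire < 1L ||
        object@nOffspringPerDam < 1L)
        msg <- c(msg, "design sizes must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Simulated offspring cohort with growth trajectories
#'
#' A \code{GrowthCohort} extends \linkS4class{SummarizedExperiment}. The
#' single assay, \code{"weight"}, holds body weights with one row per time
#' point (0 .. nSteps) and one column per offspring; \code{colData} carries
#' the pedigree links (\code{sire}, \code{dam}, \code{partner}), the three
#' breeding values (\code{A_GR}, \code{A_D}, \code{A_I}) and the
#' environmental effects (\code{Ep}, \code{E_D}, \code{E_I}) of each
#' offspring. The metadata list keeps the generating \code{GrowthScenario},
#' the parent table (sire and dam breeding values plus the dam-to-sire
#' mating), the seeds used by each simulation stage, and a diagnostic count
#' of negative weights.
#'
#' Before [simulateGrowth()] has run, the assay is all \code{NA}; before
#' [pairIndividuals()] has run, \code{partner} is all \code{NA}.
#'
#' @seealso [sampleOffspring()], [pairIndividuals()], [simulateGrowth()],
#'   [simulateCohort()].
#' @export
setClass("GrowthCohort", contains = "SummarizedExperiment")

#' Sparse parent-incidence design for the sire-dam trait models
#'
#' Response vector (final body weight, one record per offspring) plus a
#' sparse incidence matrix with exactly two 1s per row: the columns of the
#' record's own sire and dam (\code{mode = "direct"}) or of its partner's
#' sire and dam (\code{mode = "indirect"}).
#'
#' @slot response numeric vector of final weights (g).
#' @slot incidence \code{dgCMatrix}, records x parents.
#' @slot parentIds character; column identities, sires then dams.
#' @slot mode \code{"direct"} or \code{"indirect"}.
#' @seealso [buildParentDesign()], [fitParentModel()].
#' @export
setClass("ParentDesign",
    representation(
        response = "numeric",
        incidence = "dgCMatrix",
        parentIds = "character",
        mode = "character"
    )
)

setValidity("ParentDesign", function(object) {
    msg <- character()
    if (length(object@response) != nrow(object@incidence))
        msg <- c(msg, "response length must equal nrow(incidence)")
    if (length(object@parentIds) != ncol(object@incidence))
        msg <- c(msg, "parentIds length must equal ncol(incidence)")
    if (!object@mode %in% c("direct", "indirect"))
        msg <- c(msg, "mode must be 'direct' or 'indirect'")
    rs <- Matrix::rowSums(object@incidence)
    if (length(rs) && (any(rs != 2) || any(object@incidence@x != 1)))
        msg <- c(msg, "each record must carry exactly two 1s")
    if (length(msg)) msg else TRUE
})

#' REML fit of a one-variance-component mixed model
#'
#' Virtual parent of [SireModelFit-class] and [ParentModelFit-class]: an
#' intercept-only mixed model \eqn{y = \mu 1 + Z u + e} with
#' \eqn{u \sim N(0, \sigma^2_u I)} fitted by restricted maximum likelihood,
#' with best linear unbiased predictions (BLUPs) of \eqn{u} at the REML
#' estimates.
#'
#' @slot sigma2u numeric; variance of the random effect (>= 0, 0 at the
#'   boundary).
#' @slot sigma2e numeric; residual variance.
#' @slot mu numeric; estimated intercept (generalized least squares).
#' @slot loglik numeric; restricted log-likelihood at the estimates.
#' @slot blup named numeric; predicted random effects.
#' @slot converged logical.
#' @export
setClass("VarianceModelFit",
    representation(
        sigma2u = "numeric",
        sigma2e = "numeric",
        mu = "numeric",
        loglik = "numeric",
        blup = "numeric",
        converged = "logical",
        "VIRTUAL"
    )
)

setValidity("VarianceModelFit", function(object) {
    msg <- character()
    if (object@sigma2u < 0) msg <- c(msg, "sigma2u must be >= 0")
    if (object@sigma2e <= 0) msg <- c(msg, "sigma2e must be > 0")
    if (length(msg)) msg else TRUE
})

#' One-way sire model fit on log family variances
#'
#' REML fit of \eqn{y = \mu + Z_s s + e} where \eqn{y} is the log
#' within-family variance of final weight (direct model) or the log variance
#' of the family's partners' final weights (indirect model) and \eqn{s} is a
#' random sire effect. See [fitSireModel()].
#'
#' @slot response character; \code{"direct"} or \code{"indirect"}.
#' @export
setClass("SireModelFit", contains = "VarianceModelFit",
         representation(response = "character"))

#' Sire-dam mixed model fit on individual final weight
#'
#' REML fit of \eqn{y = \mu + Z_p p + e} over a pooled sire+dam effect
#' vector with one shared variance component. See [fitParentModel()].
#'
#' @slot mode character; \code{"direct"} or \code{"indirect"}.
#' @export
setClass("ParentModelFit", contains = "VarianceModelFit",
         representation(mode = "character"))

#' Correlations between predicted effects and simulated breeding values
#'
#' Per-replicate and aggregated Pearson correlations between the predicted
#' random effects of one or more fitted models and the simulated breeding
#' values (A_GR, A_D, A_I). Sire-model predictions are correlated with
#' sire-level truths; sire-dam predictions with the pooled sire+dam truths.
#'
#' @slot scenario the generating \linkS4class{GrowthScenario}.
#' @slot nReplicates integer; replicates attempted.
#' @slot replicates data.frame with columns \code{replicate}, \code{model},
#'   \code{truth}, \code{r} (one row per correlation per replicate).
#' @slot summary data.frame with columns \code{model}, \code{truth},
#'   \code{mean_r}, \code{se_r}, \code{pooled_r}, \code{n_replicates}.
#' @slot failures integer; replicates dropped because a fit failed.
#' @slot seed integer; master seed.
#' @seealso [runScenario()], [reportSummary()].
#' @export
setClass("CorrelationReport",
    representation(
        scenario = "GrowthScenario",
        nReplicates = "integer",
        replicates = "data.frame",
        summary = "data.frame",
        failures = "integer",
        seed = "integer"
    )
)

#' Configuration of a full simulation-and-estimation run
#'
#' @slot scenarios integer vector of canonical scenario ids (1-21).
#' @slot purpose character; \code{"variability"}, \code{"trait"} or
#'   \code{"both"}.
#' @slot replicates integer; replicates per scenario and purpose.
#' @slot seed integer master seed.
#' @slot scale character; \code{"paper"} (100 sires x 100 dams/sire) or
#'   \code{"reduced"} (100 x 20, 50 offspring/dam for variability).
#' @slot outDir character; output directory.
#' @seealso [readRunConfig()], [runStudy()].
#' @export
setClass("RunConfig",
    representation(
        scenarios = "integer",
        purpose = "character",
        replicates = "integer",
        seed = "integer",
        scale = "character",
        outDir = "character"
    )
)

setValidity("RunConfig", function(object) {
    msg <- character()
    if (!length(object@scenarios) || any(is.na(object@scenarios)) ||
        any(object@scenarios < 1L) || any(object@scenarios > 21L))
        msg <- c(msg, "field 'scenarios': ids must be in 1..21")
    if (length(object@purpose) != 1L ||
        !object@purpose %in% c("variability", "trait", "both"))
        msg <- c(msg, "field 'purpose': must be 'variability', 'trait' or 'both'")
    if (length(object@replicates) != 1L || is.na(object@replicates) ||
        object@replicates < 1L)
        msg <- c(msg, "field 'replicates': must be a positive integer")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "field 'seed': must be a single integer")
    if (length(object@scale) != 1L || !object@scale %in% c("paper", "reduced"))
        msg <- c(msg, "field 'scale': must be 'paper' or 'reduced'")
    if (length(object@outDir) != 1L || !nzchar(object@outDir))
        msg <- c(msg, "field 'out_dir': must be a non-empty path")
    if (length(msg)) msg else TRUE
})
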
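#' Construct a growth scenario
#'
#' Builds a \linkS4class{GrowthScenario} with the default parameterization of
#' the simulation study: mean growth rate and starting weight of 10 g,
#' genetic SD of growth 1 g, heritability 0.5 and repeatability 0.7 of growth
#' rate at \eqn{b = 0}, ten growth increments, and a total SD of the
#' interaction coefficient \eqn{b} of 0.03 split equally over its four
#' components (\eqn{\sigma_{AD} = \sigma_{AI} = \sigma_{ED} = \sigma_{EI} =
#' 0.015}). The mating design is 100 sires, each mated to 100 dams, with 100
#' offspring per dam for variability analyses and 10 for trait analyses.
#'
#' @param bBar mean interaction coefficient; -0.05 (competition), 0
#'   (neutral) or +0.05 (cooperation) in the canonical grid.
#' @param sigmaAD,sigmaAI genetic SDs of the direct and indirect effects on
#'   \eqn{b}.
#' @param sigmaAGR genetic SD of growth rate (g). The phenotypic,
#'   permanent-environmental and temporary-environmental variances scale with
#'   it; see [deriveVariances()].
#' @param sigmaED,sigmaEI environmental SDs of the direct and indirect
#'   effects on \eqn{b}.
#' @param purpose \code{"variability"} or \code{"trait"}; selects the
#'   default \code{nOffspringPerDam} (100 vs 10).
#' @param muGR,startWeight,h2,repeatability,nSteps growth-model parameters.
#' @param geneticCorr 3x3 correlation matrix over (A_GR, A_D, A_I);
#'   identity by default.
#' @param nSires,nDamsPerSire,nOffspringPerDam design sizes;
#'   \code{nOffspringPerDam} defaults from \code{purpose}.
#' @param scenarioId,label canonical-grid bookkeeping; inferred from
#'   \code{bBar} when missing.
#' @return A validated \linkS4class{GrowthScenario}.
#' @examples
#' sc <- GrowthScenario(bBar = -0.05)
#' deriveVariances(sc)
#' @export
GrowthScenario <- function(bBar = -0.05, sigmaAD = 0.015, sigmaAI = 0.015,
                           sigmaAGR = 1, sigmaED = 0.015, sigmaEI = 0.015,
                           purpose = c("variability", "trait"),
                           muGR = 10, startWeight = 10, h2 = 0.5,
                           repeatability = 0.7, nSteps = 10L,
                           geneticCorr = diag(3), nSires = 100L,
                           nDamsPerSire = 100L, nOffspringPerDam = NULL,
                           scenarioId = NA_integer_, label = NULL) {
    purpose <- match.arg(purpose)
    if (is.null(nOffspringPerDam))
        nOffspringPerDam <- if (purpose == "variability") 100L else 10L
    if (is.null(label))
        label <- if (bBar < 0) "competition"
                 else if (bBar > 0) "cooperation" else "neutral"
    dimnames(geneticCorr) <- rep(list(c("A_GR", "A_D", "A_I")), 2L)
    new("GrowthScenario",
        scenarioId = as.integer(scenarioId), label = label, purpose = purpose,
        muGR = muGR, startWeight = startWeight, sigmaAGR = sigmaAGR,
        bBar = bBar, sigmaAD = sigmaAD, sigmaAI = sigmaAI,
        sigmaED = sigmaED, sigmaEI = sigmaEI, h2 = h2,
        repeatability = repeatability, nSteps = as.integer(nSteps),
        geneticCorr = geneticCorr, nSires = as.integer(nSires),
        nDamsPerSire = as.integer(nDamsPerSire),
        nOffspringPerDam = as.integer(nOffspringPerDam))
}

#' Variance budget of growth rate implied by a scenario
#'
#' The phenotypic variance of growth rate is defined at \eqn{b = 0} as
#' \eqn{\sigma^2_P = \sigma^2_{A_{GR}} / h^2}. The permanent environmental
#' variance is \eqn{(repeatability - h^2)\,\sigma^2_P} and the temporary
#' (per-time-step) environmental variance \eqn{(1 - repeatability)\,
#' \sigma^2_P}; with the default \eqn{h^2 = 0.5} and repeatability 0.7 these
#' are \eqn{0.2\,\sigma^2_P} and \eqn{0.3\,\sigma^2_P}. All three rescale
#' automatically when \code{sigmaAGR} changes (e.g. 18, 3.6 and 5.4 g^2 at
#' \code{sigmaAGR = 3}).
#'
#' @param scenario a \linkS4class{GrowthScenario}.
#' @return Named numeric: \code{sigma_P2}, \code{sigma_Ep2}, \code{sigma_Et2}
#'   (g^2).
#' @examples
#' deriveVariances(GrowthScenario())            # 2, 0.4, 0.6
#' deriveVariances(GrowthScenario(sigmaAGR = 3))# 18, 3.6, 5.4
#' @export
deriveVariances <- function(scenario) {
    stopifnot(is(scenario, "GrowthScenario"))
    if (scenario@h2 <= 0)
        stop("h2 must be positive")
    sigmaP2 <- scenario@sigmaAGR^2 / scenario@h2
    c(sigma_P2 = sigmaP2,
      sigma_Ep2 = (scenario@repeatability - scenario@h2) * sigmaP2,
      sigma_Et2 = (1 - scenario@repeatability) * sigmaP2)
}

#' The canonical 21-scenario grid
#'
#' Returns the full grid of simulated scenarios: competition
#' (\eqn{\bar b = -0.05}), neutral (0) and cooperation (+0.05) crossed with
#' the default, tripled and one-third values of \eqn{\sigma_{AD}},
#' \eqn{\sigma_{AI}} and \eqn{\sigma_{A_{GR}}}, one parameter varied at a
#' time. The grid ships as a machine-readable table
#' (\code{system.file("extdata", "scenario_grid.csv", package = "IGEvar")}).
#'
#' @param purpose \code{"variability"} or \code{"trait"}; passed to
#'   [GrowthScenario()].
#' @param ids optional integer subset of scenario ids to return.
#' @return Named list of \linkS4class{GrowthScenario} objects
#'   (\code{"scenario_1"} ...).
#' @examples
#' sc1 <- canonicalScenarios(ids = 1)[[1]]
#' scenarioLabel(sc1)
#' @export
canonicalScenarios <- function(purpose = c("variability", "trait"),
                               ids = NULL) {
    purpose <- match.arg(purpose)
    grid <- scenarioGrid()
    if (!is.null(ids)) {
        if (!all(ids %in% grid$scenario))
            stop("unknown scenario id(s): ",
                 paste(setdiff(ids, grid$scenario), collapse = ", "))
        grid <- grid[match(ids, grid$scenario), , drop = FALSE]
    }
    out <- lapply(seq_len(nrow(grid)), function(i) {
        GrowthScenario(bBar = grid$b_bar[i], sigmaAD = grid$sigma_AD[i],
                       sigmaAI = grid$sigma_AI[i], sigmaAGR = grid$sigma_AGR[i],
                       purpose = purpose, scenarioId = grid$scenario[i],
                       label = grid$label[i])
    })
    names(out) <- paste0("scenario_", grid$scenario)
    out
}

#' @rdname canonicalScenarios
#' @return \code{scenarioGrid} returns the grid itself as a data.frame with
#'   columns \code{scenario}, \code{label}, \code{b_bar}, \code{sigma_AD},
#'   \code{sigma_AI}, \code{sigma_AGR}.
#' @export
scenarioGrid <- function() {
    path <- system.file("extdata", "scenario_grid.csv", package = "IGEvar",
                        mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Rescale a scenario's mating design
#'
#' The \code{"paper"} scale is the design of the full study (100 sires x 100
#' dams per sire, 100 or 10 offspring per dam). The \code{"reduced"} preset
#' (100 sires x 20 dams per sire, 50 offspring per dam for variability) runs
#' about an order of magnitude faster; with fewer and smaller families it
#' attenuates the precision of family-variance records, so correlations are
#' somewhat weaker than at full scale.
#'
#' @param scenario a \linkS4class{GrowthScenario}.
#' @param scale \code{"paper"} or \code{"reduced"}.
#' @return The rescaled scenario.
#' @export
applyScale <- function(scenario, scale = c("paper", "reduced")) {
    scale <- match.arg(scale)
    if (scale == "paper") {
        scenario@nSires <- 100L
        scenario@nDamsPerSire <- 100L
        scenario@nOffspringPerDam <-
            if (scenario@purpose == "variability") 100L else 10L
    } else {
        scenario@nSires <- 100L
        scenario@nDamsPerSire <- 20L
        scenario@nOffspringPerDam <-
            if (scenario@purpose == "variability") 50L else 10L
    }
    validObject(scenario)
    scenario
}
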
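#' Build the sire-dam incidence design for the trait models
#'
#' One record per offspring, response = final body weight. In
#' \code{"direct"} mode the record's row of the incidence matrix has 1s in
#' the columns of the offspring's own sire and dam; in \code{"indirect"}
#' mode, in the columns of its social partner's sire and dam. Sires and dams
#' are pooled into a single parent-effect vector (sires first), as the
#' sire-dam model assumes one shared variance for both.
#'
#' @param cohort a simulated, paired \linkS4class{GrowthCohort}.
#' @param mode \code{"direct"} or \code{"indirect"}.
#' @return A \linkS4class{ParentDesign}.
#' @examples
#' sc <- GrowthScenario(nSires = 2L, nDamsPerSire = 1L, nOffspringPerDam = 1L,
#'                      purpose = "trait")
#' d <- buildParentDesign(simulateCohort(sc, 3), "direct")
#' as.matrix(d@incidence)
#' @export
buildParentDesign <- function(cohort, mode = c("direct", "indirect")) {
    mode <- match.arg(mode)
    stopifnot(is(cohort, "GrowthCohort"))
    cd <- colData(cohort)
    y <- finalWeight(cohort)
    if (anyNA(y))
        stop("cohort has no simulated weights; run simulateGrowth() first")
    if (anyNA(cd$partner))
        stop("cohort is not paired")
    parents <- parentTable(cohort)
    nS <- nrow(parents$sires)
    nD <- nrow(parents$dams)
    sire <- cd$sire
    dam <- cd$dam
    if (anyNA(sire) || anyNA(dam))
        stop("missing parent id in cohort")
    if (mode == "indirect") {
        sire <- sire[cd$partner]
        dam <- dam[cd$partner]
    }
    n <- length(y)
    Z <- Matrix::sparseMatrix(i = c(seq_len(n), seq_len(n)),
                              j = c(sire, nS + dam), x = 1,
                              dims = c(n, nS + nD))
    new("ParentDesign", response = as.numeric(y), incidence = Z,
        parentIds = c(parents$sires$id, parents$dams$id), mode = mode)
}

#' Fit a sire-dam mixed model on final weight by REML
#'
#' Fits \eqn{y = \mu + Z_p p + e} with a pooled parent effect
#' \eqn{p \sim N(0, \sigma^2_p I)} over all sires and dams (one shared
#' variance, parents unrelated) by REML. The likelihood is profiled in the
#' variance ratio \eqn{\gamma = \sigma^2_p / \sigma^2_e} and maximized by a
#' 1-D bounded search; all linear algebra runs on the sparse normal
#' equations with a cached symbolic Cholesky factorization, so paper-scale
#' designs (10^5 records x 10,100 parents) fit in seconds. Predicted parent
#' effects are BLUPs at the REML estimates; under a purely additive
#' simulation each parent effect estimates half the parent's breeding
#' value, so \eqn{\sigma^2_p} estimates a quarter of the additive variance.
#'
#' @param design a \linkS4class{ParentDesign} from [buildParentDesign()].
#' @return A \linkS4class{ParentModelFit}; \code{blup()} is named by parent
#'   id (sires first, then dams).
#' @export
fitParentModel <- function(design) {
    stopifnot(is(design, "ParentDesign"))
    validObject(design)
    if (ncol(design@incidence) < 2L)
        stop("need at least 2 parents")
    res <- tryCatch(
        .remlOneVariance(design@response, design@incidence),
        error = function(e) stop("sire-dam REML failed: ",
                                 conditionMessage(e), call. = FALSE))
    new("ParentModelFit", mode = design@mode,
        sigma2u = res$sigma2u, sigma2e = res$sigma2e, mu = res$mu,
        loglik = res$loglik,
        blup = setNames(res$blup, design@parentIds),
        converged = res$converged)
}
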
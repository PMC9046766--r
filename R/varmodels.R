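#' Log within-family variance records for the variability models
#'
#' For every sire-dam family the function computes two responses from the
#' final body weights: \code{y_direct}, the natural log of the unbiased
#' sample variance of the family's own offspring (the classical measure of
#' the family's phenotypic variability), and \code{y_indirect}, the log of
#' the sample variance of those offspring's social partners (the
#' variability the family induces in its partners). Each record is treated
#' as an observation on the sire, so a sire has \code{nDamsPerSire} records.
#'
#' @param cohort a simulated, paired \linkS4class{GrowthCohort}.
#' @return data.frame with one row per sire-dam family: \code{sire_id},
#'   \code{dam_id}, \code{sire} and \code{dam} (1-based indices),
#'   \code{family_size}, \code{y_direct}, \code{y_indirect}.
#' @examples
#' sc <- GrowthScenario(nSires = 4L, nDamsPerSire = 3L, nOffspringPerDam = 8L)
#' rec <- familyVarianceRecords(simulateCohort(sc, seed = 11))
#' nrow(rec)  # 12 families
#' @export
familyVarianceRecords <- function(cohort) {
    stopifnot(is(cohort, "GrowthCohort"))
    cd <- colData(cohort)
    w <- finalWeight(cohort)
    if (anyNA(w))
        stop("cohort has no simulated weights; run simulateGrowth() first")
    if (anyNA(cd$partner))
        stop("cohort is not paired")
    fam <- cd$dam                         # one family per dam (mated once)
    nFam <- max(fam)
    sizes <- tabulate(fam, nFam)
    if (any(sizes < 2L))
        stop("every family needs at least 2 offspring to compute a variance")
    wp <- w[cd$partner]
    logGroupVar <- function(v) {
        s1 <- rowsum(v, fam)
        s2 <- rowsum(v * v, fam)
        vr <- (s2 - s1^2 / sizes) / (sizes - 1)
        vr <- pmax(vr, 0)                 # guard tiny negative rounding
        if (any(vr <= 0))
            stop("zero within-family variance; cannot log-transform")
        log(as.numeric(vr))
    }
    parents <- parentTable(cohort)
    damSire <- parents$dams$sire
    data.frame(
        sire_id = parents$sires$id[damSire],
        dam_id = parents$dams$id,
        sire = damSire,
        dam = seq_len(nFam),
        family_size = sizes,
        y_direct = logGroupVar(w),
        y_indirect = logGroupVar(wp))
}

#' Fit a one-way sire model to log family variances by REML
#'
#' Fits \eqn{y = \mu + Z_s s + e} with \eqn{s \sim N(0, \sigma^2_s I)} by
#' restricted maximum likelihood, where \eqn{y} is \code{y_direct} (direct
#' model: each sire's effect on the variability of its own offspring) or
#' \code{y_indirect} (indirect model: the sire's effect on the variability
#' of its offspring's partners). The likelihood is profiled in the variance
#' ratio; on a balanced design the interior REML solution coincides with the
#' one-way ANOVA closed form \eqn{\hat\sigma^2_s = (MSB - MSW)/n}, and a
#' negative closed-form value corresponds to the boundary estimate
#' \eqn{\hat\sigma^2_s = 0}. Predicted sire effects are BLUPs at the REML
#' estimates.
#'
#' @param records data.frame from [familyVarianceRecords()].
#' @param response \code{"direct"} or \code{"indirect"}.
#' @return A \linkS4class{SireModelFit}; \code{blup()} is named by sire id.
#' @examples
#' rec <- data.frame(sire_id = c("S1", "S1", "S2", "S2"),
#'                   sire = c(1L, 1L, 2L, 2L),
#'                   y_direct = c(1, 3, 5, 7))
#' fit <- fitSireModel(rec, "direct")
#' varianceComponents(fit)  # sigma2_u = 7, sigma2_e = 2
#' @export
fitSireModel <- function(records, response = c("direct", "indirect")) {
    response <- match.arg(response)
    ycol <- paste0("y_", response)
    if (!ycol %in% names(records))
        stop("records lack column ", ycol)
    sire <- records$sire
    nS <- max(sire)
    if (nS < 2L)
        stop("need at least 2 sires")
    if (any(tabulate(sire, nS) < 2L))
        stop("need at least 2 records per sire")
    y <- records[[ycol]]
    Z <- .indicatorMatrix(sire, nS)
    res <- .remlOneVariance(y, Z)
    sireIds <- if (!is.null(records$sire_id))
        unique(records$sire_id[order(records$sire)])
    else paste0("S", seq_len(nS))
    new("SireModelFit", response = response,
        sigma2u = res$sigma2u, sigma2e = res$sigma2e, mu = res$mu,
        loglik = res$loglik, blup = setNames(res$blup, sireIds),
        converged = res$converged)
}
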
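#' Pearson correlation with degenerate-input guards
#'
#' Standard product-moment correlation, returning \code{NA} (rather than an
#' error or \code{NaN}) when either vector is constant, which happens for
#' variability models on degenerate simulations with no genetic variance in
#' \eqn{b}.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The correlation, or \code{NA_real_} if undefined.
#' @examples
#' pearson(c(1, 2, 3), c(2, 1, 4))  # 0.5
#' @export
pearson <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (length(x) < 3L)
        stop("need at least 3 observations")
    if (sd(x) == 0 || sd(y) == 0 || anyNA(x) || anyNA(y))
        return(NA_real_)
    as.numeric(stats::cor(x, y))
}

# Fit the two models appropriate to the cohort's purpose and return, per
# model, the predicted effects aligned with the true breeding values of the
# corresponding level (sires for variability models, pooled sires + dams for
# trait models).
.fitAndAlign <- function(cohort) {
    scenario <- metadata(cohort)$scenario
    parents <- parentTable(cohort)
    if (scenario@purpose == "variability") {
        rec <- familyVarianceRecords(cohort)
        truth <- parents$sires[c("A_GR", "A_D", "A_I")]
        list(
            `direct-variability` = list(
                fit = fitSireModel(rec, "direct"), truth = truth),
            `indirect-variability` = list(
                fit = fitSireModel(rec, "indirect"), truth = truth))
    } else {
        truth <- rbind(parents$sires[c("A_GR", "A_D", "A_I")],
                       parents$dams[c("A_GR", "A_D", "A_I")])
        list(
            `direct-trait` = list(
                fit = fitParentModel(buildParentDesign(cohort, "direct")),
                truth = truth),
            `indirect-trait` = list(
                fit = fitParentModel(buildParentDesign(cohort, "indirect")),
                truth = truth))
    }
}

#' Simulate a scenario repeatedly and correlate predictions with truth
#'
#' For each replicate the scenario is simulated afresh, the two models of
#' its purpose are fitted (variability purpose: direct and indirect sire
#' models on log family variance; trait purpose: direct and indirect
#' sire-dam models on final weight), and the predicted random effects are
#' correlated with the simulated breeding values: sire-model predictions
#' with the sires' (A_GR, A_D, A_I), sire-dam predictions with the pooled
#' sire + dam values. Reported are the across-replicate mean and standard
#' error of each correlation and, for transparency, the correlation of the
#' data pooled over replicates. Replicates whose fits fail are excluded and
#' counted.
#'
#' @param scenario a \linkS4class{GrowthScenario}.
#' @param nReplicates replicates to run; defaults to the study's counts
#'   (100 for variability, 10 for trait).
#' @param seed master seed; replicate r uses sub-seeds derived from
#'   \code{seed + r} via [deriveSeed()].
#' @return A \linkS4class{CorrelationReport}.
#' @examples
#' sc <- GrowthScenario(nSires = 20L, nDamsPerSire = 5L,
#'                      nOffspringPerDam = 20L)
#' rep1 <- runScenario(sc, nReplicates = 1, seed = 5)
#' reportSummary(rep1)
#' @export
runScenario <- function(scenario, nReplicates = NULL, seed = 1L) {
    stopifnot(is(scenario, "GrowthScenario"))
    if (is.null(nReplicates))
        nReplicates <- if (scenario@purpose == "variability") 100L else 10L
    nReplicates <- as.integer(nReplicates)
    truths <- c("A_GR", "A_D", "A_I")
    rows <- list()
    pooled <- list()   # model -> truth -> list(est, true)
    failures <- 0L
    for (r in seq_len(nReplicates)) {
        aligned <- tryCatch({
            cohort <- simulateCohort(scenario, seed = seed + r, replicate = r)
            .fitAndAlign(cohort)
        }, error = function(e) {
            warning("replicate ", r, " failed: ", conditionMessage(e),
                    call. = FALSE)
            NULL
        })
        if (is.null(aligned)) {
            failures <- failures + 1L
            next
        }
        for (model in names(aligned)) {
            est <- blup(aligned[[model]]$fit)
            truth <- aligned[[model]]$truth
            for (tr in truths) {
                rows[[length(rows) + 1L]] <- data.frame(
                    replicate = r, model = model, truth = tr,
                    r = pearson(est, truth[[tr]]))
                key <- paste(model, tr, sep = ".")
                pooled[[key]] <- list(
                    est = c(pooled[[key]]$est, est),
                    true = c(pooled[[key]]$true, truth[[tr]]))
            }
        }
    }
    reps <- if (length(rows)) do.call(rbind, rows)
            else data.frame(replicate = integer(), model = character(),
                            truth = character(), r = numeric())
    summ <- list()
    for (key in names(pooled)) {
        parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
        sel <- reps$model == parts[1L] & reps$truth == parts[2L]
        rv <- reps$r[sel]
        rv <- rv[!is.na(rv)]
        summ[[key]] <- data.frame(
            model = parts[1L], truth = parts[2L],
            mean_r = if (length(rv)) mean(rv) else NA_real_,
            se_r = if (length(rv) > 1L) sd(rv) / sqrt(length(rv))
                   else NA_real_,
            pooled_r = pearson(pooled[[key]]$est, pooled[[key]]$true),
            n_replicates = length(rv))
    }
    summ <- if (length(summ)) do.call(rbind, c(summ, make.row.names = FALSE))
            else data.frame(model = character(), truth = character(),
                            mean_r = numeric(), se_r = numeric(),
                            pooled_r = numeric(), n_replicates = integer())
    new("CorrelationReport", scenario = scenario,
        nReplicates = nReplicates, replicates = reps, summary = summ,
        failures = failures, seed = as.integer(seed))
}

#' Mean correlation for one model/truth pair of a report
#'
#' Convenience lookup in [reportSummary()].
#'
#' @param report a \linkS4class{CorrelationReport}.
#' @param model one of \code{"direct-variability"},
#'   \code{"indirect-variability"}, \code{"direct-trait"},
#'   \code{"indirect-trait"}.
#' @param truth \code{"A_GR"}, \code{"A_D"} or \code{"A_I"}.
#' @return The across-replicate mean Pearson correlation.
#' @export
meanCorrelation <- function(report, model, truth) {
    s <- reportSummary(report)
    row <- s[s$model == model & s$truth == truth, , drop = FALSE]
    if (nrow(row) != 1L)
        stop("no unique summary row for ", model, " / ", truth)
    row$mean_r
}
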
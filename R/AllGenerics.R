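#' Accessors for scenario and model-fit objects
#'
#' Small accessor generics for the package's S4 classes. \code{scenarioId},
#' \code{scenarioLabel} and \code{scenarioPurpose} read scenario identity;
#' \code{varianceComponents} returns the REML estimates of a fit as a named
#' vector; \code{blup} the predicted random effects; \code{remlLogLik} the
#' restricted log-likelihood; \code{isConverged} the convergence flag;
#' \code{reportSummary} and \code{reportReplicates} the aggregated and
#' per-replicate correlation tables of a \linkS4class{CorrelationReport}.
#'
#' @param object an object of the documented classes.
#' @return See each accessor's description.
#' @name accessors
#' @aliases scenarioId scenarioLabel scenarioPurpose varianceComponents blup
#'   remlLogLik isConverged reportSummary reportReplicates
#' @examples
#' sc <- GrowthScenario(bBar = 0)
#' scenarioLabel(sc)
NULL

#' @rdname accessors
#' @export
setGeneric("scenarioId", function(object) standardGeneric("scenarioId"))

#' @rdname accessors
#' @export
setGeneric("scenarioLabel", function(object) standardGeneric("scenarioLabel"))

#' @rdname accessors
#' @export
setGeneric("scenarioPurpose",
           function(object) standardGeneric("scenarioPurpose"))

#' @rdname accessors
#' @export
setGeneric("varianceComponents",
           function(object) standardGeneric("varianceComponents"))

#' @rdname accessors
#' @export
setGeneric("blup", function(object) standardGeneric("blup"))

#' @rdname accessors
#' @export
setGeneric("remlLogLik", function(object) standardGeneric("remlLogLik"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("reportSummary", function(object) standardGeneric("reportSummary"))

#' @rdname accessors
#' @export
setGeneric("reportReplicates",
           function(object) standardGeneric("reportReplicates"))

#' @rdname accessors
#' @export
setMethod("scenarioId", "GrowthScenario", function(object) object@scenarioId)

#' @rdname accessors
#' @export
setMethod("scenarioLabel", "GrowthScenario", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("scenarioPurpose", "GrowthScenario",
          function(object) object@purpose)

#' @rdname accessors
#' @export
setMethod("varianceComponents", "VarianceModelFit", function(object) {
    c(sigma2_u = object@sigma2u, sigma2_e = object@sigma2e, mu = object@mu)
})

#' @rdname accessors
#' @export
setMethod("blup", "VarianceModelFit", function(object) object@blup)

#' @rdname accessors
#' @export
setMethod("remlLogLik", "VarianceModelFit", function(object) object@loglik)

#' @rdname accessors
#' @export
setMethod("isConverged", "VarianceModelFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("reportSummary", "CorrelationReport",
          function(object) object@summary)

#' @rdname accessors
#' @export
setMethod("reportReplicates", "CorrelationReport",
          function(object) object@replicates)

setMethod("show", "GrowthScenario", function(object) {
    id <- if (is.na(object@scenarioId)) "custom" else object@scenarioId
    cat(sprintf("GrowthScenario %s (%s, %s purpose)\n", id, object@label,
                object@purpose))
    cat(sprintf("  b_bar = %+.3f  sigma_AD = %.3f  sigma_AI = %.3f  sigma_AGR = %g\n",
                object@bBar, object@sigmaAD, object@sigmaAI, object@sigmaAGR))
    dv <- deriveVariances(object)
    cat(sprintf("  sigma_P2 = %g  sigma_Ep2 = %g  sigma_Et2 = %g (g^2)\n",
                dv[["sigma_P2"]], dv[["sigma_Ep2"]], dv[["sigma_Et2"]]))
    cat(sprintf("  design: %d sires x %d dams/sire x %d offspring/dam (%d offspring)\n",
                object@nSires, object@nDamsPerSire, object@nOffspringPerDam,
                object@nSires * object@nDamsPerSire * object@nOffspringPerDam))
    if (max(abs(object@geneticCorr - diag(3))) > 0)
        cat("  non-zero genetic correlations among (A_GR, A_D, A_I)\n")
})

setMethod("show", "VarianceModelFit", function(object) {
    kind <- if (is(object, "SireModelFit"))
        sprintf("%s sire model (log family variance)", object@response)
    else
        sprintf("%s sire-dam model (final weight)", object@mode)
    cat(sprintf("%s of class %s\n", kind, class(object)))
    cat(sprintf("  sigma2_u = %.6g  sigma2_e = %.6g  mu = %.6g\n",
                object@sigma2u, object@sigma2e, object@mu))
    cat(sprintf("  REML log-likelihood = %.4f  converged: %s  (%d levels)\n",
                object@loglik, object@converged, length(object@blup)))
})

setMethod("show", "CorrelationReport", function(object) {
    id <- if (is.na(object@scenario@scenarioId)) "custom"
          else object@scenario@scenarioId
    cat(sprintf("CorrelationReport: scenario %s (%s), %s purpose, %d replicate(s)\n",
                id, object@scenario@label, object@scenario@purpose,
                object@nReplicates))
    if (object@failures > 0L)
        cat(sprintf("  %d replicate(s) dropped (failed fits)\n",
                    object@failures))
    print(object@summary, digits = 3, row.names = FALSE)
})

setMethod("show", "ParentDesign", function(object) {
    cat(sprintf("ParentDesign (%s): %d records x %d parents\n",
                object@mode, nrow(object@incidence), ncol(object@incidence)))
})
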
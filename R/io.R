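#' Construct or read a run configuration
#'
#' \code{RunConfig()} builds a validated configuration in code;
#' \code{readRunConfig()} reads one from a YAML or JSON file with fields
#' \code{scenarios} (integer ids or \code{"all"}), \code{purpose}
#' (\code{"variability"}, \code{"trait"} or \code{"both"}),
#' \code{replicates}, \code{seed}, \code{scale} (\code{"paper"} or
#' \code{"reduced"}) and \code{out_dir}. Validation errors name the
#' offending field.
#'
#' @param scenarios integer scenario ids in 1..21, or \code{"all"}.
#' @param purpose,replicates,seed,scale,outDir see
#'   \linkS4class{RunConfig}.
#' @return A validated \linkS4class{RunConfig}.
#' @examples
#' cfg <- RunConfig(scenarios = 1:3, purpose = "variability",
#'                  replicates = 2, seed = 42, scale = "reduced",
#'                  outDir = tempdir())
#' @export
RunConfig <- function(scenarios = "all", purpose = "both", replicates = 5,
                      seed = 1, scale = "paper", outDir = ".") {
    if (identical(scenarios, "all"))
        scenarios <- 1:21
    new("RunConfig", scenarios = as.integer(scenarios),
        purpose = as.character(purpose), replicates = as.integer(replicates),
        seed = as.integer(seed), scale = as.character(scale),
        outDir = as.character(outDir))
}

#' @rdname RunConfig
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json}
#'   configuration file.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    raw <- switch(ext,
        yaml = , yml = yaml::read_yaml(path),
        json = jsonlite::read_json(path, simplifyVector = TRUE),
        stop("config must be YAML or JSON, got extension '", ext, "'"))
    known <- c("scenarios", "purpose", "replicates", "seed", "scale",
               "out_dir")
    unknown <- setdiff(names(raw), known)
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    pick <- function(field, default) {
        if (is.null(raw[[field]])) default else raw[[field]]
    }
    RunConfig(scenarios = pick("scenarios", "all"),
              purpose = pick("purpose", "both"),
              replicates = pick("replicates", 5),
              seed = pick("seed", 1),
              scale = pick("scale", "paper"),
              outDir = pick("out_dir", "."))
}

.configAsList <- function(config) {
    list(scenarios = config@scenarios, purpose = config@purpose,
         replicates = config@replicates, seed = config@seed,
         scale = config@scale, out_dir = config@outDir)
}

#' Run the full simulation-and-estimation study
#'
#' For every requested scenario and purpose: simulate \code{replicates}
#' cohorts, fit the two models of that purpose, correlate predictions with
#' the simulated breeding values, and write flat artifacts into
#' \code{outDir}: \code{report.csv} (one row per scenario, purpose, model
#' and breeding value, with mean, SE and pooled correlations),
#' \code{replicates.csv} (per-replicate correlations) and
#' \code{manifest.json} (the full configuration, seeds and package
#' version). Outputs contain no timestamps, so identical configuration and
#' seed reproduce byte-identical files.
#'
#' @param config a \linkS4class{RunConfig} or a path accepted by
#'   [readRunConfig()].
#' @param verbose print progress.
#' @return Invisibly, a list with the written file paths and the reports.
#' @export
runStudy <- function(config, verbose = interactive()) {
    if (is.character(config))
        config <- readRunConfig(config)
    validObject(config)
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(config@outDir))
        stop("cannot create output directory: ", config@outDir)
    purposes <- if (config@purpose == "both") c("variability", "trait")
                else config@purpose
    reports <- list()
    summaries <- list()
    repRows <- list()
    for (purpose in purposes) {
        scens <- canonicalScenarios(purpose = purpose, ids = config@scenarios)
        for (sc in scens) {
            sc <- applyScale(sc, config@scale)
            if (verbose)
                message("scenario ", scenarioId(sc), " (", purpose, ")")
            rep <- runScenario(sc, nReplicates = config@replicates,
                               seed = deriveSeed(config@seed, "replicate",
                                                 scenarioId(sc)))
            key <- sprintf("scenario_%02d_%s", scenarioId(sc), purpose)
            reports[[key]] <- rep
            s <- reportSummary(rep)
            if (nrow(s)) {
                s <- cbind(scenario = scenarioId(sc),
                           label = scenarioLabel(sc), purpose = purpose, s)
                summaries[[key]] <- s
            }
            rr <- reportReplicates(rep)
            if (nrow(rr)) {
                rr <- cbind(scenario = scenarioId(sc), purpose = purpose, rr)
                repRows[[key]] <- rr
            }
        }
    }
    reportPath <- file.path(config@outDir, "report.csv")
    replicatesPath <- file.path(config@outDir, "replicates.csv")
    manifestPath <- file.path(config@outDir, "manifest.json")
    utils::write.csv(do.call(rbind, c(summaries, make.row.names = FALSE)),
                     reportPath, row.names = FALSE)
    utils::write.csv(do.call(rbind, c(repRows, make.row.names = FALSE)),
                     replicatesPath, row.names = FALSE)
    manifest <- list(
        config = .configAsList(config),
        package = "IGEvar",
        package_version = as.character(utils::packageVersion("IGEvar")),
        scenario_seeds = vapply(
            config@scenarios,
            function(id) deriveSeed(config@seed, "replicate", id), 0L))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(report = reportPath, replicates = replicatesPath,
                   manifest = manifestPath, reports = reports))
}

#' Export a cohort as tidy CSV
#'
#' One row per offspring with pedigree links, breeding values,
#' environmental effects and the full weight trajectory
#' (\code{weight_t0} ... \code{weight_tN}).
#'
#' @param cohort a simulated \linkS4class{GrowthCohort}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
exportCohort <- function(cohort, path) {
    stopifnot(is(cohort, "GrowthCohort"))
    cd <- as.data.frame(colData(cohort))
    parents <- parentTable(cohort)
    W <- t(assay(cohort, "weight"))
    colnames(W) <- paste0("weight_", rownames(assay(cohort, "weight")))
    out <- cbind(
        data.frame(id = rownames(cd),
                   sire_id = parents$sires$id[cd$sire],
                   dam_id = parents$dams$id[cd$dam],
                   partner_id = rownames(cd)[cd$partner]),
        cd[c("A_GR", "A_D", "A_I", "Ep", "E_D", "E_I")], W)
    utils::write.csv(out, path, row.names = FALSE)
    invisible(path)
}

#' Export family-variance records as CSV
#'
#' @param records data.frame from [familyVarianceRecords()].
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
exportFamilyRecords <- function(records, path) {
    utils::write.csv(
        records[c("sire_id", "dam_id", "family_size", "y_direct",
                  "y_indirect")],
        path, row.names = FALSE)
    invisible(path)
}

#' Export a parent design in sparse-triplet CSV form
#'
#' Columns \code{record}, \code{parent} (id) and \code{value} (always 1);
#' two rows per record.
#'
#' @param design a \linkS4class{ParentDesign}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
exportParentDesign <- function(design, path) {
    stopifnot(is(design, "ParentDesign"))
    tr <- Matrix::summary(design@incidence)
    out <- data.frame(record = tr$i, parent = design@parentIds[tr$j],
                      value = tr$x)
    out <- out[order(out$record), ]
    utils::write.csv(out, path, row.names = FALSE)
    invisible(path)
}

#' Export a model fit as JSON (components) plus CSV (predicted effects)
#'
#' @param fit a \linkS4class{VarianceModelFit}.
#' @param jsonPath,csvPath output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
exportFit <- function(fit, jsonPath, csvPath) {
    stopifnot(is(fit, "VarianceModelFit"))
    comp <- as.list(varianceComponents(fit))
    comp$loglik <- remlLogLik(fit)
    comp$converged <- isConverged(fit)
    comp$class <- class(fit)[1L]
    jsonlite::write_json(comp, jsonPath, auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(id = names(blup(fit)), blup = blup(fit)),
                     csvPath, row.names = FALSE)
    invisible(c(jsonPath, csvPath))
}
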
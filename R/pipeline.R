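#' Run the full analysis pipeline on a simulated or loaded cohort
#'
#' Orchestrates the stages end to end: cohort simulation (or reading of an
#' intensity matrix plus metadata), sample QC, reactivity calling, nMAD
#' normalization, autoantibody loads, per-antigen prevalence scans, optional
#' combination-panel ROC analyses with bootstrap, PCA batch check, and the
#' paired longitudinal tests when matched timepoints exist. The resolved
#' configuration (with every threshold echoed) travels with the result, and
#' an identical configuration plus seed reproduces the bundle exactly.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{phase}{\code{"phase2"} or \code{"phase3"} to simulate, or
#'       \code{NULL} when \code{intensity}/\code{metadata} paths are given.}
#'     \item{intensity, metadata, annotation}{file paths for a real cohort
#'       (used when \code{phase} is \code{NULL}).}
#'     \item{seed}{integer root seed (simulation and bootstrap).}
#'     \item{nFactor}{cutoff multiplier; \code{NULL} uses the assay default.}
#'     \item{minValidFraction}{QC threshold (default 0.9).}
#'     \item{comparisons}{list of \code{list(groupBy=, levels=)} prevalence
#'       scans.}
#'     \item{panels}{named list of \linkS4class{AntibodyPanel} objects; each
#'       is evaluated against the first comparison's grouping.}
#'     \item{bootstrapB}{bootstrap resamples for panel curve comparison
#'       (default 500; 0 disables).}
#'   }
#' @return A list bundle: \code{se} (the \linkS4class{SeroExperiment} with
#'   calls and nmad assays), \code{loads}, \code{prevalence} (list of
#'   data.frames), \code{panels}, \code{pca}, \code{longitudinal},
#'   \code{config}.
#' @export
runPipeline <- function(config) {
    defaults <- list(phase = NULL, intensity = NULL, metadata = NULL,
                     annotation = NULL, seed = 1L, nFactor = NULL,
                     minValidFraction = 0.9, comparisons = list(),
                     panels = list(), bootstrapB = 500L)
    defaults[names(config)] <- config
    config <- defaults

    se <- if (!is.null(config$phase)) {
        simulateCohort(studyPhaseConfig(config$phase, seed = config$seed))
    } else {
        if (is.null(config$intensity))
            stop("stage ingest: need either 'phase' or an 'intensity' path",
                 call. = FALSE)
        se0 <- readIntensityMatrix(config$intensity)
        if (!is.null(config$metadata)) {
            md <- readSampleMetadata(config$metadata)
            colData(se0) <- md[colnames(se0), ]
        }
        if (!is.null(config$annotation)) {
            an <- readAntigenAnnotation(config$annotation)
            rowData(se0) <- an[rownames(se0), ]
        }
        se0
    }

    se <- qcFilter(se, minValidFraction = config$minValidFraction)
    se <- callReactivity(se, nFactor = config$nFactor)
    se <- nmadNormalize(se)
    loads <- autoantibodyLoad(se)

    prevalence <- lapply(config$comparisons, function(cmp) {
        if (!cmp$groupBy %in% colnames(colData(se)))
            stop(sprintf("stage prevalence: unknown comparison variable '%s'",
                         cmp$groupBy), call. = FALSE)
        comparePrevalence(se, cmp$groupBy, cmp$levels,
                          antigens = cmp$antigens,
                          bh = isTRUE(cmp$bh))
    })

    panels <- lapply(config$panels, function(panel) {
        if (!length(config$comparisons))
            stop("stage panel: panels require at least one comparison",
                 call. = FALSE)
        cmp <- config$comparisons[[1L]]
        gv <- as.character(colData(se)[[cmp$groupBy]])
        keep <- gv %in% cmp$levels
        lbl <- factor(gv[keep], levels = rev(cmp$levels))  # level 1 positive
        pos <- panelCall(se, panel)[keep]
        score <- panelScore(se, panel)[keep]
        binPanel <- AntibodyPanel(panel@antigens, panel@k, "count_positive")
        binScore <- panelScore(se, binPanel)[keep]
        n1 <- sum(gv[keep] == cmp$levels[1L] & !is.na(pos))
        n2 <- sum(gv[keep] == cmp$levels[2L] & !is.na(pos))
        a <- sum(pos == 1 & gv[keep] == cmp$levels[1L], na.rm = TRUE)
        c_ <- sum(pos == 1 & gv[keep] == cmp$levels[2L], na.rm = TRUE)
        out <- list(
            panel = panel,
            contingency = c(a = a, b = n1 - a, c = c_, d = n2 - c_),
            fisher = fisherExact2x2(a, n1 - a, c_, n2 - c_),
            roc_intensity = rocCurve(score, lbl),
            roc_binary = rocCurve(binScore, lbl))
        if (config$bootstrapB >= 100)
            out$bootstrap <- bootstrapCompareAUC(score, binScore, lbl,
                                                 B = config$bootstrapB,
                                                 seed = config$seed)
        out
    })

    pca <- pcaBatchCheck(se, nComponents = 2)

    longitudinal <- NULL
    tp <- colData(se)$timepoint
    if (!is.null(tp) &&
        all(c("diagnosis", "remission") %in% as.character(tp))) {
        series <- buildMatchedSeries(se)
        if (length(series) >= 2L)
            longitudinal <- list(
                n_series = length(series),
                load_test = pairedLoadTest(series))
    }

    list(se = se, loads = loads, prevalence = prevalence, panels = panels,
         pca = pca, longitudinal = longitudinal, config = config)
}

#' Export plot-ready report tables from a pipeline bundle
#'
#' Writes the analysis outputs as plain TSV/JSON files that plotting or
#' reporting tools can consume directly: the binary call matrix and nMAD
#' matrix (heatmap inputs), per-sample cutoff table, loads, one prevalence
#' table per comparison, per-panel contingency counts and ROC curve points,
#' the QC exclusion report, and the resolved configuration as JSON.
#'
#' @param bundle output of [runPipeline()].
#' @param dir output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
exportReportTables <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    se <- bundle$se
    paths <- character()
    wt <- function(df, name) {
        p <- file.path(dir, name)
        write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
        paths <<- c(paths, p)
    }
    wt(data.frame(antigen_id = rownames(se), callMatrix(se),
                  check.names = FALSE), "calls.tsv")
    wt(data.frame(antigen_id = rownames(se), round(nmadMatrix(se), 4),
                  check.names = FALSE), "nmad.tsv")
    wt(data.frame(sample_id = colnames(se),
                  cutoff = colData(se)$cutoff,
                  sample_median = colData(se)$sample_median,
                  sample_mad = colData(se)$sample_mad,
                  degenerate = colData(se)$degenerate,
                  n_factor = metadata(se)$n_factor), "cutoffs.tsv")
    wt(data.frame(sample_id = names(bundle$loads), load = bundle$loads),
       "loads.tsv")
    for (i in seq_along(bundle$prevalence))
        wt(bundle$prevalence[[i]], sprintf("prevalence_%d.tsv", i))
    for (nm in names(bundle$panels)) {
        pn <- bundle$panels[[nm]]
        wt(data.frame(t(pn$contingency), p = pn$fisher$p,
                      odds_ratio = pn$fisher$odds_ratio),
           sprintf("panel_%s_contingency.tsv", nm))
        roc <- pn$roc_intensity
        wt(data.frame(threshold = roc@thresholds,
                      sensitivity = roc@sensitivity,
                      specificity = roc@specificity),
           sprintf("panel_%s_roc.tsv", nm))
    }
    writeExclusionReport(se, file.path(dir, "qc_exclusions.jsonl"))
    cfg <- bundle$config
    cfg$panels <- lapply(cfg$panels, function(p)
        list(antigens = p@antigens, k = p@k, scoreType = p@scoreType))
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, null = "null")
    paths <- c(paths, file.path(dir, c("qc_exclusions.jsonl", "config.json")))
    invisible(paths)
}
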
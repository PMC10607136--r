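#' Accessors for SeroExperiment assays and calling results
#'
#' \code{mfi()} returns the raw intensity matrix (antigens x samples);
#' \code{callMatrix()} the binary reactivity calls added by
#' [callReactivity()]; \code{nmadMatrix()} the normalized deviation scores
#' added by [nmadNormalize()]; \code{truthMatrix()} the planted
#' seropositivity of a simulated cohort; \code{cutoffs()} the per-sample
#' reactivity cutoffs; \code{isDegenerate()} the per-sample flag for samples
#' whose MAD was zero.
#'
#' @param x a \linkS4class{SeroExperiment}.
#' @return A matrix (assay accessors) or named numeric/logical vector
#'   (per-sample accessors).
#' @name seroAccessors
NULL

.assayOrStop <- function(x, name, hint) {
    if (!name %in% assayNames(x))
        stop(sprintf("assay '%s' not present; run %s first", name, hint),
             call. = FALSE)
    assay(x, name)
}

#' @rdname seroAccessors
#' @export
mfi <- function(x) assay(x, "MFI")

#' @rdname seroAccessors
#' @export
callMatrix <- function(x) .assayOrStop(x, "calls", "callReactivity()")

#' @rdname seroAccessors
#' @export
nmadMatrix <- function(x) .assayOrStop(x, "nmad", "nmadNormalize()")

#' @rdname seroAccessors
#' @export
truthMatrix <- function(x) .assayOrStop(x, "truth", "simulateCohort()")

#' @rdname seroAccessors
#' @export
cutoffs <- function(x) {
    if (is.null(colData(x)$cutoff))
        stop("no cutoffs recorded; run callReactivity() first", call. = FALSE)
    stats::setNames(colData(x)$cutoff, colnames(x))
}

#' @rdname seroAccessors
#' @export
isDegenerate <- function(x) {
    d <- colData(x)$degenerate
    if (is.null(d)) d <- rep(FALSE, ncol(x))
    stats::setNames(d, colnames(x))
}

#' @rdname seroAccessors
#' @export
qcExclusions <- function(x) {
    ex <- metadata(x)$qc_exclusions
    if (is.null(ex))
        ex <- data.frame(sample_id = character(), valid_fraction = numeric(),
                         reason = character())
    ex
}

setMethod("show", "SeroExperiment", function(object) {
    cat(sprintf("SeroExperiment: %d antigens x %d samples\n",
                nrow(object), ncol(object)))
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
    if (!is.null(colData(object)$group)) {
        tb <- table(droplevels(factor(colData(object)$group)))
        cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
            "\n")
    }
    nf <- metadata(object)$n_factor
    if (!is.null(nf))
        cat(sprintf("  reactivity calls at median + %g x MAD\n", nf))
    ex <- metadata(object)$qc_exclusions
    if (!is.null(ex) && nrow(ex))
        cat(sprintf("  %d sample(s) removed by QC\n", nrow(ex)))
})

setMethod("show", "AntibodyPanel", function(object) {
    cat(sprintf("AntibodyPanel: %d antigens, positive if >= %d reactive, score = %s\n",
                length(object@antigens), object@k, object@scoreType))
    cat(" ", paste(object@antigens, collapse = ", "), "\n")
})

setMethod("show", "RocCurve", function(object) {
    cat(sprintf("RocCurve: AUC = %.3f (%d positives, %d negatives, %d thresholds)\n",
                object@auc, object@nPositive, object@nNegative,
                length(object@thresholds)))
})

setMethod("show", "SimulationConfig", function(object) {
    n <- object@nSamplesPerGroup
    cat("SimulationConfig:",
        paste(sprintf("%s=%d", names(n), n), collapse = ", "),
        sprintf("x %d antigens (%s), seed %d\n",
                object@nAntigens, object@assayType, object@seed))
})

#' Area under a ROC curve
#' @param object a \linkS4class{RocCurve}.
#' @return the AUC as a number in \[0, 1\].
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

#' @rdname auc
#' @export
setMethod("auc", "RocCurve", function(object) object@auc)
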
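#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames colData colData<- rowData rowData<-
NULL

# Controlled vocabularies for sample metadata. group/site/timepoint are
# structural (invalid values reject); anca/phenotype/sex fall back to the
# explicit "unknown" level.
.GROUP_LEVELS     <- c("AAV", "GCA", "PMR", "HC")
.SITE_LEVELS      <- c("MUW", "UCAM", "UMCG", "SYNTH")
.TIMEPOINT_LEVELS <- c("diagnosis", "remission", "relapse", "single")
.ANCA_LEVELS      <- c("MPO", "PR3", "negative", "unknown")
.PHENOTYPE_LEVELS <- c("MPA", "GPA", "not_applicable", "unknown")
.SEX_LEVELS       <- c("M", "F", "unknown")
.ORGAN_LEVELS     <- c("kidney", "ENT", "respiratory")

#' SeroExperiment: antigen-array reactivity container
#'
#' A \linkS4class{SummarizedExperiment} holding raw median fluorescence
#' intensities (assay \code{"MFI"}) for antigens (rows) measured in serum
#' samples (columns), together with derived assays added by the analysis
#' functions: \code{"calls"} (binary reactivity, [callReactivity()]),
#' \code{"nmad"} (normalized deviation scores, [nmadNormalize()]) and, for
#' simulated cohorts, \code{"truth"} (planted seropositivity,
#' [simulateCohort()]). Sample metadata (clinical group, site, timepoint,
#' ANCA serotype, phenotype, ...) lives in \code{colData}, antigen annotation
#' (gene symbol, fragment coordinates) in \code{rowData}.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#'
#' @section Validity:
#' The \code{"MFI"} assay must be present, numeric, finite and nonnegative;
#' antigen and sample identifiers must be present and unique.
#'
#' @seealso [SeroExperiment()] for construction, [mfi()], [callMatrix()],
#'   [nmadMatrix()], [truthMatrix()], [cutoffs()] for access.
#' @export
setClass("SeroExperiment", contains = "SummarizedExperiment")

setValidity("SeroExperiment", function(object) {
    msg <- character()
    if (!"MFI" %in% assayNames(object))
        return("assay 'MFI' is required")
    m <- assay(object, "MFI")
    if (!is.numeric(m))
        msg <- c(msg, "assay 'MFI' must be numeric")
    bad <- which(!is.finite(m) | m < 0)
    if (length(bad)) {
        rc <- arrayInd(bad[1L], dim(m))
        msg <- c(msg, sprintf(
            "MFI values must be finite and >= 0; first offender at antigen '%s', sample '%s'",
            rownames(m)[rc[1L]], colnames(m)[rc[2L]]))
    }
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "antigen (row) and sample (column) names are required")
    dup <- unique(rownames(object)[duplicated(rownames(object))])
    if (length(dup))
        msg <- c(msg, sprintf("duplicate antigen id: '%s'", dup[1L]))
    dup <- unique(colnames(object)[duplicated(colnames(object))])
    if (length(dup))
        msg <- c(msg, sprintf("duplicate sample id: '%s'", dup[1L]))
    if (length(msg)) msg else TRUE
})

#' Construct a SeroExperiment
#'
#' @param mfi numeric matrix of raw median fluorescence intensities with
#'   antigens in rows and samples in columns; dimnames are required and must
#'   be unique. All values must be finite and nonnegative.
#' @param sampleData optional \code{DataFrame}/\code{data.frame} of per-sample
#'   metadata, one row per column of \code{mfi} (see [readSampleMetadata()]
#'   for the expected columns).
#' @param antigenData optional per-antigen annotation, one row per row of
#'   \code{mfi}.
#' @param truth optional binary matrix of planted seropositivity with the same
#'   dimensions as \code{mfi} (used by the simulator).
#' @param metadata optional list of experiment-level metadata (e.g.
#'   \code{assay_type}, \code{default_n_factor}).
#'
#' @return A \linkS4class{SeroExperiment}.
#' @examples
#' m <- matrix(rlnorm(12, 5, 0.3), nrow = 4,
#'             dimnames = list(paste0("AG", 1:4), paste0("S", 1:3)))
#' se <- SeroExperiment(m)
#' se
#' @export
SeroExperiment <- function(mfi, sampleData = NULL, antigenData = NULL,
                           truth = NULL, metadata = list()) {
    mfi <- as.matrix(mfi)
    storage.mode(mfi) <- "double"
    assays <- list(MFI = mfi)
    if (!is.null(truth)) {
        truth <- as.matrix(truth)
        stopifnot(identical(dim(truth), dim(mfi)))
        dimnames(truth) <- dimnames(mfi)
        storage.mode(truth) <- "integer"
        assays$truth <- truth
    }
    args <- list(assays = assays, metadata = metadata)
    if (!is.null(sampleData)) args$colData <- DataFrame(sampleData)
    if (!is.null(antigenData)) args$rowData <- DataFrame(antigenData)
    se <- do.call(SummarizedExperiment, args)
    new("SeroExperiment", se)
}

#' Panel of autoantibodies with a combination rule
#'
#' Defines a combination panel (for example the three kinesin fragments used
#' to separate anti-MPO positive MPA from anti-PR3 positive GPA patients):
#' the member antigen ids, the binary rule "panel-positive if at least
#' \code{k} member antibodies are called reactive", and the numeric score
#' used for ROC analysis on intensity data.
#'
#' @slot antigens ordered character vector of member antigen ids.
#' @slot k integer, minimum number of reactive members for panel positivity.
#' @slot scoreType one of \code{"sum_nmad"} (default; sum of the members'
#'   nMAD scores), \code{"max_nmad"}, \code{"count_positive"} (number of
#'   reactive members, the "binary data" score).
#' @export
setClass("AntibodyPanel", representation(
    antigens = "character", k = "integer", scoreType = "character"))

setValidity("AntibodyPanel", function(object) {
    msg <- character()
    if (length(object@antigens) < 1L || anyDuplicated(object@antigens))
        msg <- c(msg, "antigens must be a non-empty set of unique ids")
    if (length(object@k) != 1L || is.na(object@k) ||
        object@k < 1L || object@k > length(object@antigens))
        msg <- c(msg, "k must satisfy 1 <= k <= panel size")
    if (!object@scoreType %in% c("sum_nmad", "max_nmad", "count_positive"))
        msg <- c(msg, "scoreType must be sum_nmad, max_nmad or count_positive")
    if (length(msg)) msg else TRUE
})

#' @param antigens,k,scoreType see slot documentation.
#' @return An \code{AntibodyPanel}.
#' @examples
#' AntibodyPanel(c("KIN001", "KIN002", "KIN003"), k = 2)
#' @rdname AntibodyPanel-class
#' @export
AntibodyPanel <- function(antigens, k = 1,
                          scoreType = c("sum_nmad", "max_nmad", "count_positive")) {
    new("AntibodyPanel", antigens = as.character(antigens),
        k = as.integer(k), scoreType = match.arg(scoreType))
}

#' ROC curve of a per-sample score against a binary class label
#'
#' Produced by [rocCurve()]. Thresholds are placed at midpoints between
#' adjacent unique score values (plus sentinels below and above the range); a
#' sample is predicted positive when its score strictly exceeds the
#' threshold. The AUC is the trapezoidal area, identical to the Mann-Whitney
#' probability with ties counted 1/2.
#'
#' @slot thresholds numeric, decreasing.
#' @slot sensitivity,specificity numeric, aligned with \code{thresholds}.
#' @slot auc area under the curve in \[0, 1\].
#' @slot nPositive,nNegative class sizes after removing missing scores.
#' @export
setClass("RocCurve", representation(
    thresholds = "numeric", sensitivity = "numeric", specificity = "numeric",
    auc = "numeric", nPositive = "integer", nNegative = "integer"))

setValidity("RocCurve", function(object) {
    msg <- character()
    if (any(object@sensitivity < 0 | object@sensitivity > 1) ||
        any(object@specificity < 0 | object@specificity > 1))
        msg <- c(msg, "sensitivity and specificity must lie in [0, 1]")
    if (object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must lie in [0, 1]")
    if (is.unsorted(rev(object@thresholds)))
        msg <- c(msg, "thresholds must be decreasing")
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic bead-array cohort generator
#'
#' Parameters of the generative model used by [simulateCohort()]. Intensities
#' are multiplicative on the raw scale (additive on the log scale): antigen
#' background x sample scale x site batch effect x seropositivity boost x
#' lognormal measurement noise. All \code{*LogSd} parameters are standard
#' deviations on the natural-log scale.
#'
#' @slot nSamplesPerGroup named integer vector, samples per clinical group
#'   (names from AAV, GCA, PMR, HC). For AAV these are diagnosis samples;
#'   matched remission/relapse samples are added via
#'   \code{longitudinalFraction} and \code{nRelapse}.
#' @slot nAntigens number of antigen fragments on the array.
#' @slot baselineLogMean location of the antigen backgrounds (log MFI).
#' @slot baselineLogSd per-measurement noise sd (log scale).
#' @slot antigenLogSd spread of antigen-specific background locations.
#' @slot sampleScaleLogSd spread of per-sample multiplicative scales.
#' @slot siteEffectLogSd spread of per-site batch effects.
#' @slot positiveEffectLogMean,positiveEffectLogSd log-scale location/spread
#'   of the multiplicative boost applied to planted seropositive values.
#' @slot prevalence matrix of planted seropositivity probabilities, groups in
#'   rows (named), antigens in columns.
#' @slot longitudinalFraction fraction of AAV subjects with a matched
#'   remission sample.
#' @slot nRelapse number of AAV subjects (among the longitudinal ones) with
#'   an additional relapse sample; relapse reuses the diagnosis truth.
#' @slot positivePersistence probability that a planted positive at diagnosis
#'   remains positive at remission.
#' @slot assayType free-text label ("bead_targeted", "bead_kinesin",
#'   "planar") used to pick the default cutoff multiplier.
#' @slot seed integer root seed; per-group substreams are derived from it so
#'   that adding a group does not perturb the draws of the others.
#' @export
setClass("SimulationConfig", representation(
    nSamplesPerGroup = "integer", nAntigens = "integer",
    baselineLogMean = "numeric", baselineLogSd = "numeric",
    antigenLogSd = "numeric", sampleScaleLogSd = "numeric",
    siteEffectLogSd = "numeric",
    positiveEffectLogMean = "numeric", positiveEffectLogSd = "numeric",
    prevalence = "matrix", longitudinalFraction = "numeric",
    nRelapse = "integer", positivePersistence = "numeric",
    assayType = "character", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    g <- names(object@nSamplesPerGroup)
    if (is.null(g) || !all(g %in% .GROUP_LEVELS))
        msg <- c(msg, sprintf("group names must be among: %s",
                              paste(.GROUP_LEVELS, collapse = ", ")))
    if (any(object@nSamplesPerGroup < 1L))
        msg <- c(msg, "all group sizes must be >= 1")
    if (object@nAntigens < 1L)
        msg <- c(msg, "nAntigens must be >= 1")
    sds <- c(object@baselineLogSd, object@antigenLogSd,
             object@sampleScaleLogSd, object@siteEffectLogSd,
             object@positiveEffectLogSd)
    if (any(sds < 0))
        msg <- c(msg, "scale parameters must be >= 0")
    p <- object@prevalence
    if (any(p < 0 | p > 1))
        msg <- c(msg, "prevalence probabilities must lie in [0, 1]")
    if (!identical(sort(rownames(p)), sort(g)))
        msg <- c(msg, "prevalence rows must match the configured groups")
    if (ncol(p) != object@nAntigens)
        msg <- c(msg, "prevalence must have one column per antigen")
    if (object@longitudinalFraction < 0 || object@longitudinalFraction > 1 ||
        object@positivePersistence < 0 || object@positivePersistence > 1)
        msg <- c(msg, "fractions/probabilities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
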
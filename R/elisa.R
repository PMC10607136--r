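#' @importFrom stats sd
NULL

#' ELISA positivity cutoff from healthy controls
#'
#' The verification-assay cutoff: mean + 3 standard deviations (sample SD,
#' n - 1 denominator) of the healthy-control OD450 readings.
#'
#' @param controlODs numeric vector of control optical densities (>= 2
#'   values, finite and nonnegative).
#' @return The cutoff value.
#' @examples
#' elisaCutoff(c(0.15, 0.20, 0.25))   # 0.2 + 3 * 0.05 = 0.35
#' @export
elisaCutoff <- function(controlODs) {
    if (length(controlODs) < 2L)
        stop("need at least 2 healthy-control OD values", call. = FALSE)
    if (any(!is.finite(controlODs) | controlODs < 0))
        stop("OD values must be finite and >= 0", call. = FALSE)
    mean(controlODs) + 3 * sd(controlODs)
}

#' Call ELISA positivity on a plate
#'
#' A test sample is positive when its OD450 strictly exceeds the
#' healthy-control cutoff (mean + 3 SD); readings equal to the cutoff are
#' negative, and control samples are never called.
#'
#' @param plate data.frame with columns \code{sample_id}, \code{od450} and
#'   logical \code{is_control}.
#' @return list with \code{cutoff} and \code{calls}, a named logical vector
#'   over the test (non-control) samples.
#' @export
elisaCall <- function(plate) {
    req <- c("sample_id", "od450", "is_control")
    miss <- setdiff(req, colnames(plate))
    if (length(miss))
        stop(sprintf("plate is missing column(s): %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
    ctrl <- as.logical(plate$is_control)
    cut <- elisaCutoff(plate$od450[ctrl])
    test <- plate[!ctrl, , drop = FALSE]
    if (any(!is.finite(test$od450) | test$od450 < 0))
        stop("OD values must be finite and >= 0", call. = FALSE)
    list(cutoff = cut,
         calls = stats::setNames(test$od450 > cut,
                                 as.character(test$sample_id)))
}

#' Concordance between bead-array and ELISA calls for one antigen
#'
#' Cross-platform verification: tabulates agreement between the bead-array
#' reactivity calls and the ELISA calls for the overlapping samples, and
#' tests the association of the two call sets with [fisherExact2x2()].
#'
#' @param beadCalls named binary/logical vector of bead-array calls (or a
#'   \linkS4class{SeroExperiment} after [callReactivity()] together with
#'   \code{antigen}).
#' @param elisaCalls named logical vector from [elisaCall()].
#' @param antigen antigen id, required when \code{beadCalls} is a
#'   SeroExperiment.
#' @return list with \code{table} (2x2 bead x ELISA), \code{agreement}
#'   (fraction concordant), \code{n} and \code{p} (Fisher exact).
#' @export
crossPlatformConcordance <- function(beadCalls, elisaCalls, antigen = NULL) {
    if (is(beadCalls, "SeroExperiment")) {
        if (is.null(antigen))
            stop("antigen id required with a SeroExperiment", call. = FALSE)
        beadCalls <- callMatrix(beadCalls)[antigen, ]
    }
    common <- intersect(names(beadCalls), names(elisaCalls))
    if (!length(common))
        stop("no overlapping sample ids", call. = FALSE)
    b <- as.logical(beadCalls[common]); e <- as.logical(elisaCalls[common])
    keep <- !is.na(b) & !is.na(e)
    b <- b[keep]; e <- e[keep]
    tab <- table(bead = factor(b, c(TRUE, FALSE)),
                 elisa = factor(e, c(TRUE, FALSE)))
    ft <- fisherExact2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    list(table = tab, agreement = mean(b == e), n = length(b), p = ft$p)
}
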
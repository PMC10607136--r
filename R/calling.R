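#' @importFrom stats median mad
NULL

.robustStats <- function(x, madConstant = FALSE) {
    med <- median(x)
    c(median = med,
      mad = mad(x, center = med, constant = if (madConstant) 1.4826 else 1))
}

#' Per-sample reactivity cutoff: median + n x MAD
#'
#' Computes the robust seropositivity cutoff for one sample from its raw
#' intensities across all antigens on the array: the sample median plus
#' \code{nFactor} median absolute deviations from that median. By default the
#' MAD is the plain median absolute deviation (no 1.4826 normal-consistency
#' constant), matching the cutoff formula as used for the arrays; set
#' \code{madConstant = TRUE} for the consistency-scaled variant.
#'
#' @param x numeric vector of raw intensities for one sample (length >= 2,
#'   all finite).
#' @param nFactor positive multiplier n (assay-specific; see
#'   [defaultNFactor()]).
#' @param madConstant apply the 1.4826 consistency constant to the MAD.
#' @return The cutoff value, with attributes \code{median}, \code{mad} and
#'   \code{degenerate} (\code{TRUE} when the sample MAD is zero, in which
#'   case the cutoff is not usable for calling).
#' @examples
#' sampleCutoff(1:101, nFactor = 2)   # median 51, MAD 25 -> 101
#' @export
sampleCutoff <- function(x, nFactor, madConstant = FALSE) {
    if (length(x) < 2L) stop("need at least 2 intensities", call. = FALSE)
    if (!all(is.finite(x))) stop("intensities must be finite", call. = FALSE)
    if (nFactor <= 0) stop("nFactor must be > 0", call. = FALSE)
    rs <- .robustStats(x, madConstant)
    structure(unname(rs["median"] + nFactor * rs["mad"]),
              median = unname(rs["median"]), mad = unname(rs["mad"]),
              degenerate = rs[["mad"]] == 0)
}

.resolveNFactor <- function(x, nFactor) {
    if (!is.null(nFactor)) return(nFactor)
    nf <- metadata(x)$default_n_factor
    if (is.null(nf))
        stop("nFactor not given and no default recorded for this experiment",
             call. = FALSE)
    nf
}

#' Call binary reactivity against per-sample robust cutoffs
#'
#' Transforms raw intensities into binary reactive/non-reactive calls: an
#' antibody is positive in a sample when its intensity passes that sample's
#' cutoff median + n x MAD (strictly greater by default). Cutoffs, sample
#' medians/MADs and the degenerate flag are recorded in \code{colData}; the
#' multiplier in \code{metadata(x)$n_factor}.
#'
#' Samples with MAD = 0 cannot be called; by default
#' (\code{degenerate = "exclude"}) their calls are set to \code{NA} and
#' flagged, with \code{degenerate = "fallback"} their MAD is replaced by the
#' smallest nonzero sample MAD in the cohort.
#'
#' @param x a \linkS4class{SeroExperiment} with an \code{"MFI"} assay.
#' @param nFactor cutoff multiplier; defaults to the assay-specific value
#'   recorded by the simulator/reader (30 planar, 50 targeted bead, 20
#'   kinesin bead).
#' @param madConstant apply the 1.4826 consistency constant (default off).
#' @param strict call positive on \code{value > cutoff} (default) rather than
#'   \code{>=}.
#' @param degenerate handling of MAD = 0 samples.
#' @return \code{x} with an integer \code{"calls"} assay added.
#' @export
callReactivity <- function(x, nFactor = NULL, madConstant = FALSE,
                           strict = TRUE,
                           degenerate = c("exclude", "fallback")) {
    stopifnot(is(x, "SeroExperiment"))
    degenerate <- match.arg(degenerate)
    nFactor <- .resolveNFactor(x, nFactor)
    if (nFactor <= 0) stop("nFactor must be > 0", call. = FALSE)
    m <- mfi(x)
    med <- apply(m, 2L, median)
    madv <- vapply(seq_len(ncol(m)), function(j)
        mad(m[, j], center = med[j], constant = if (madConstant) 1.4826 else 1),
        numeric(1L))
    degen <- madv == 0
    madUse <- madv
    if (any(degen) && degenerate == "fallback") {
        if (all(degen))
            stop("every sample has MAD = 0; no fallback available",
                 call. = FALSE)
        madUse[degen] <- min(madv[!degen])
    }
    cut <- med + nFactor * madUse
    cmp <- if (strict) `>` else `>=`
    calls <- matrix(as.integer(cmp(m, rep(cut, each = nrow(m)))),
                    nrow = nrow(m), dimnames = dimnames(m))
    if (any(degen) && degenerate == "exclude") {
        calls[, degen] <- NA_integer_
        warning(sprintf("%d sample(s) with MAD = 0 excluded from calling",
                        sum(degen)), call. = FALSE)
    }
    assay(x, "calls") <- calls
    colData(x)$sample_median <- unname(med)
    colData(x)$sample_mad <- unname(madv)
    colData(x)$cutoff <- unname(cut)
    colData(x)$degenerate <- unname(degen)
    metadata(x)$n_factor <- nFactor
    metadata(x)$call_strict <- strict
    metadata(x)$mad_constant <- madConstant
    x
}

#' Normalize intensities to nMAD deviation scores
#'
#' Computes, per value, the number of median absolute deviations separating
#' it from its sample's median: \code{(x - median(sample)) / MAD(sample)}.
#' This removes per-sample intensity-scale differences; with strict-greater
#' calling and no consistency constant, thresholding the scores at n is
#' identical to [callReactivity()] with multiplier n. Samples with MAD = 0
#' get missing scores and are flagged degenerate.
#'
#' @param x a \linkS4class{SeroExperiment}.
#' @return \code{x} with a numeric \code{"nmad"} assay added and sample
#'   medians/MADs in \code{colData}.
#' @export
nmadNormalize <- function(x) {
    stopifnot(is(x, "SeroExperiment"))
    m <- mfi(x)
    med <- apply(m, 2L, median)
    madv <- vapply(seq_len(ncol(m)), function(j)
        mad(m[, j], center = med[j], constant = 1), numeric(1L))
    degen <- madv == 0
    scores <- sweep(m, 2L, med, `-`)
    scores <- sweep(scores, 2L, ifelse(degen, NA_real_, madv), `/`)
    if (any(degen))
        warning(sprintf("%d sample(s) with MAD = 0 set to missing scores",
                        sum(degen)), call. = FALSE)
    assay(x, "nmad") <- scores
    colData(x)$sample_median <- unname(med)
    colData(x)$sample_mad <- unname(madv)
    colData(x)$degenerate <- unname(degen)
    x
}

#' Choose the cutoff multiplier by capping cohort-wide antigen positivity
#'
#' The multiplier n of the median + n x MAD cutoff is assay-specific and, for
#' bead arrays, is set by inspecting the distribution of each antigen's
#' intensities across all samples. This function makes that inspection
#' explicit and deterministic: for each candidate multiplier it computes
#' every antigen's cohort-wide positivity rate and returns the smallest
#' candidate for which no antigen exceeds \code{targetMaxPrevalence}. If none
#' qualifies the largest candidate is returned with a warning.
#'
#' @param x a \linkS4class{SeroExperiment}.
#' @param candidates ascending vector of candidate multipliers.
#' @param targetMaxPrevalence maximum tolerated per-antigen positivity rate.
#' @param madConstant passed to [callReactivity()].
#' @return list with \code{nFactor} (the chosen multiplier) and
#'   \code{diagnostics}, a per-candidate table of the antigen positivity
#'   distribution (max, 95th percentile, mean).
#' @export
selectNFactor <- function(x, candidates, targetMaxPrevalence,
                          madConstant = FALSE) {
    stopifnot(length(candidates) > 0, !is.unsorted(candidates),
              targetMaxPrevalence > 0, targetMaxPrevalence <= 1)
    diag <- do.call(rbind, lapply(candidates, function(n) {
        calls <- callMatrix(callReactivity(x, nFactor = n,
                                           madConstant = madConstant))
        rate <- rowMeans(calls, na.rm = TRUE)
        data.frame(n_factor = n, max_prevalence = max(rate),
                   p95_prevalence = unname(stats::quantile(rate, 0.95)),
                   mean_prevalence = mean(rate))
    }))
    ok <- diag$max_prevalence <= targetMaxPrevalence
    if (any(ok)) {
        chosen <- candidates[which(ok)[1L]]
    } else {
        chosen <- candidates[length(candidates)]
        warning(sprintf(
            "no candidate keeps every antigen below %.2f; returning largest (%g)",
            targetMaxPrevalence, chosen), call. = FALSE)
    }
    list(nFactor = chosen, diagnostics = diag)
}

#' Autoantibody load: reactive antigens per sample
#'
#' Counts, for each sample, the number of antigens called reactive,
#' optionally restricted to a subset (e.g. one kinesin subfamily). Samples
#' excluded as degenerate have missing load.
#'
#' @param x a \linkS4class{SeroExperiment} after [callReactivity()], or a
#'   binary calls matrix (antigens x samples).
#' @param antigens optional vector of antigen ids to count over.
#' @return Named integer vector of per-sample loads.
#' @export
autoantibodyLoad <- function(x, antigens = NULL) {
    calls <- if (is(x, "SeroExperiment")) callMatrix(x) else as.matrix(x)
    if (!is.null(antigens)) {
        miss <- setdiff(antigens, rownames(calls))
        if (length(miss))
            stop(sprintf("unknown antigen id(s): %s",
                         paste(miss, collapse = ", ")), call. = FALSE)
        calls <- calls[antigens, , drop = FALSE]
    }
    loads <- colSums(calls)
    storage.mode(loads) <- "integer"
    loads
}
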
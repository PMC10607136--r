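#' @importFrom stats binom.test
NULL

#' Assemble matched longitudinal series per subject
#'
#' Groups samples by subject and keeps subjects with at least two distinct
#' timepoints (e.g. diagnosis and remission), carrying the per-timepoint
#' autoantibody loads and binary calls. Subjects with a single timepoint are
#' dropped with a message.
#'
#' @param x a \linkS4class{SeroExperiment} after [callReactivity()], whose
#'   \code{colData} carries \code{subject_id} and \code{timepoint}.
#' @return Named list (by subject) of lists with \code{subject_id},
#'   \code{samples} (sample ids named by timepoint), \code{loads} (named by
#'   timepoint) and \code{calls} (antigens x timepoints matrix).
#' @export
buildMatchedSeries <- function(x) {
    cd <- colData(x)
    if (is.null(cd$subject_id) || is.null(cd$timepoint))
        stop("colData must carry subject_id and timepoint", call. = FALSE)
    calls <- callMatrix(x)
    loads <- autoantibodyLoad(x)
    key <- paste(cd$subject_id, cd$timepoint)
    dup <- unique(key[duplicated(key)])
    if (length(dup))
        stop(sprintf("duplicate (subject, timepoint): '%s'", dup[1L]),
             call. = FALSE)
    bySubj <- split(seq_len(ncol(x)), as.character(cd$subject_id))
    multi <- Filter(function(idx) length(idx) >= 2L, bySubj)
    nDropped <- length(bySubj) - length(multi)
    if (nDropped)
        message(sprintf("%d subject(s) with a single timepoint excluded",
                        nDropped))
    if (!length(multi)) {
        warning("no subjects with matched timepoints", call. = FALSE)
        return(list())
    }
    lapply(multi, function(idx) {
        tp <- as.character(cd$timepoint[idx])
        list(subject_id = as.character(cd$subject_id[idx][1L]),
             samples = stats::setNames(colnames(x)[idx], tp),
             loads = stats::setNames(loads[idx], tp),
             calls = `colnames<-`(calls[, idx, drop = FALSE], tp))
    })
}

.completePairs <- function(series, timepoints) {
    Filter(function(s) all(timepoints %in% names(s$samples)), series)
}

#' Paired test of autoantibody load across two timepoints
#'
#' Two-sided Wilcoxon signed-rank test on the within-subject load
#' differences between two matched timepoints; zero differences are dropped
#' per the standard convention, and a series in which every difference is
#' zero is reported as p = 1 with a degenerate flag.
#'
#' @param series output of [buildMatchedSeries()].
#' @param timepoints the two timepoints, first minus second
#'   (default diagnosis vs remission).
#' @return list with \code{p}, \code{median_difference}, \code{n_pairs} and
#'   \code{degenerate}.
#' @export
pairedLoadTest <- function(series, timepoints = c("diagnosis", "remission")) {
    stopifnot(length(timepoints) == 2L)
    ser <- .completePairs(series, timepoints)
    if (length(ser) < 2L)
        stop("need at least 2 complete pairs", call. = FALSE)
    d <- vapply(ser, function(s)
        as.numeric(s$loads[[timepoints[1L]]] - s$loads[[timepoints[2L]]]),
        numeric(1L))
    d <- d[!is.na(d)]
    if (all(d == 0))
        return(list(p = 1, median_difference = 0, n_pairs = length(d),
                    degenerate = TRUE))
    ht <- suppressWarnings(stats::wilcox.test(d))
    list(p = ht$p.value, median_difference = stats::median(d),
         n_pairs = length(d), degenerate = FALSE)
}

#' Exact McNemar test of per-antigen serostatus across two timepoints
#'
#' Compares positivity for one antigen between two matched timepoints using
#' only the discordant pairs: the number of subjects losing positivity
#' (positive then negative) versus gaining it, tested against a symmetric
#' exact binomial. Zero discordant pairs give p = 1; concordant pairs never
#' affect the p-value.
#'
#' @param series output of [buildMatchedSeries()].
#' @param antigen antigen id.
#' @param timepoints the two timepoints (default diagnosis, remission).
#' @return list with \code{n_pos_to_neg}, \code{n_neg_to_pos},
#'   \code{n_pairs} and \code{p}.
#' @export
pairedPositivityTest <- function(series, antigen,
                                 timepoints = c("diagnosis", "remission")) {
    stopifnot(length(timepoints) == 2L)
    ser <- .completePairs(series, timepoints)
    if (!length(ser))
        stop("no complete pairs for these timepoints", call. = FALSE)
    st <- vapply(ser, function(s) {
        if (!antigen %in% rownames(s$calls))
            stop(sprintf("unknown antigen '%s'", antigen), call. = FALSE)
        c(s$calls[antigen, timepoints[1L]], s$calls[antigen, timepoints[2L]])
    }, numeric(2L))
    ok <- !is.na(st[1L, ]) & !is.na(st[2L, ])
    st <- st[, ok, drop = FALSE]
    n10 <- sum(st[1L, ] == 1 & st[2L, ] == 0)
    n01 <- sum(st[1L, ] == 0 & st[2L, ] == 1)
    p <- if (n10 + n01 == 0) 1 else
        binom.test(n10, n10 + n01, 0.5)$p.value
    list(n_pos_to_neg = n10, n_neg_to_pos = n01, n_pairs = ncol(st), p = p)
}
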
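#' Binary combination-panel positivity
#'
#' A sample is panel-positive when at least \code{k} of the panel's member
#' antibodies are called reactive (k = 1 gives the "at least one of the
#' three" rule, k = 2 the "at least two of the three" rule). Samples with
#' missing calls for any member yield \code{NA}.
#'
#' @param x a \linkS4class{SeroExperiment} after [callReactivity()], or a
#'   binary calls matrix (antigens x samples).
#' @param panel an \linkS4class{AntibodyPanel}.
#' @return Named integer vector (1 = panel positive) over samples.
#' @export
panelCall <- function(x, panel) {
    stopifnot(is(panel, "AntibodyPanel"))
    calls <- if (is(x, "SeroExperiment")) callMatrix(x) else as.matrix(x)
    miss <- setdiff(panel@antigens, rownames(calls))
    if (length(miss))
        stop(sprintf("panel antigen(s) not in call matrix: %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
    hits <- colSums(calls[panel@antigens, , drop = FALSE])
    out <- as.integer(hits >= panel@k)
    names(out) <- colnames(calls)
    out
}

#' Numeric panel score for ROC analysis
#'
#' Combines the panel members into one per-sample score: the sum of the
#' members' nMAD scores (default, the "intensity data" score), their
#' maximum, or the count of reactive members (the "binary data" score, a 0 to
#' panel-size integer giving a stepwise ROC curve). Degenerate samples yield
#' a missing score.
#'
#' @param x a \linkS4class{SeroExperiment} with the assays required by the
#'   panel's score type (\code{"nmad"} for the nMAD scores, \code{"calls"}
#'   for \code{count_positive}).
#' @param panel an \linkS4class{AntibodyPanel}.
#' @return Named numeric vector over samples.
#' @export
panelScore <- function(x, panel) {
    stopifnot(is(x, "SeroExperiment"), is(panel, "AntibodyPanel"))
    src <- if (panel@scoreType == "count_positive") callMatrix(x)
           else nmadMatrix(x)
    miss <- setdiff(panel@antigens, rownames(src))
    if (length(miss))
        stop(sprintf("panel antigen(s) not in matrix: %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
    sub <- src[panel@antigens, , drop = FALSE]
    out <- switch(panel@scoreType,
                  sum_nmad = colSums(sub),
                  max_nmad = apply(sub, 2L, max),
                  count_positive = colSums(sub))
    stats::setNames(as.numeric(out), colnames(src))
}

#' ROC curve of a score against a binary label
#'
#' Sweeps thresholds over the observed score range (midpoints between
#' adjacent unique values, plus sentinels) with "positive if score >
#' threshold", and computes the AUC by the trapezoidal rule — numerically
#' identical to the Mann-Whitney probability with ties counted 1/2. Samples
#' with missing scores or labels are excluded pairwise.
#'
#' @param scores numeric per-sample scores (higher = more disease-like).
#' @param labels binary class per sample: logical, 0/1, or a 2-level factor
#'   whose \emph{second} level is the positive class.
#' @return A \linkS4class{RocCurve}.
#' @export
rocCurve <- function(scores, labels) {
    if (is.factor(labels)) labels <- labels == levels(labels)[2L]
    labels <- as.logical(labels)
    keep <- !is.na(scores) & !is.na(labels)
    scores <- scores[keep]; labels <- labels[keep]
    nP <- sum(labels); nN <- sum(!labels)
    if (nP == 0L || nN == 0L)
        stop("both classes must be present", call. = FALSE)
    u <- sort(unique(scores))
    thr <- c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2, u[length(u)] + 1)
    thr <- rev(thr)   # decreasing: (0,0) corner first
    sens <- vapply(thr, function(t) sum(scores > t & labels) / nP, numeric(1L))
    spec <- vapply(thr, function(t) sum(scores <= t & !labels) / nN,
                   numeric(1L))
    fpr <- 1 - spec
    aucVal <- sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
    new("RocCurve", thresholds = thr, sensitivity = sens,
        specificity = spec, auc = aucVal,
        nPositive = as.integer(nP), nNegative = as.integer(nN))
}

# Rank-based AUC used internally by the bootstrap (fast path, same value as
# the trapezoidal curve; the equality is asserted in the test suite).
.aucRank <- function(scores, labels) {
    r <- rank(scores)
    nP <- sum(labels); nN <- sum(!labels)
    (sum(r[labels]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Operating point of a ROC curve
#'
#' \code{"youden"} maximizes sensitivity + specificity - 1 (ties broken
#' toward higher specificity); \code{"fixed_specificity"} returns the best
#' sensitivity among points with specificity at least \code{value}.
#'
#' @param roc a \linkS4class{RocCurve}.
#' @param criterion selection rule.
#' @param value required minimum specificity for
#'   \code{"fixed_specificity"}.
#' @return list with \code{specificity}, \code{sensitivity},
#'   \code{threshold}.
#' @export
operatingPoint <- function(roc, criterion = c("youden", "fixed_specificity"),
                           value = NULL) {
    criterion <- match.arg(criterion)
    if (criterion == "youden") {
        j <- roc@sensitivity + roc@specificity - 1
        best <- which(j == max(j))
        i <- best[which.max(roc@specificity[best])]
    } else {
        ok <- roc@specificity >= value
        if (!any(ok))
            stop(sprintf("specificity %.3f unattainable", value),
                 call. = FALSE)
        cand <- which(ok)
        i <- cand[which.max(roc@sensitivity[cand])]
    }
    list(specificity = roc@specificity[i], sensitivity = roc@sensitivity[i],
         threshold = roc@thresholds[i])
}

#' Paired bootstrap comparison of two ROC curves
#'
#' Compares the AUCs of two scores measured on the same samples with a
#' paired nonparametric bootstrap: samples are resampled with replacement,
#' stratified by class (so no resample is degenerate), both AUCs are
#' recomputed on each resample, and the two-sided p-value is taken from the
#' percentile position of zero in the AUC-difference distribution.
#' Deterministic given \code{seed}.
#'
#' @param scores1,scores2 numeric scores over the same samples.
#' @param labels binary class labels (see [rocCurve()]).
#' @param B number of bootstrap resamples (>= 100; default 2000).
#' @param seed integer seed for the resampling.
#' @return list with \code{delta} (AUC1 - AUC2 on the original data),
#'   \code{auc1}, \code{auc2}, \code{ci} (percentile 95\% CI of the
#'   difference), \code{p}, \code{B} and \code{seed}.
#' @export
bootstrapCompareAUC <- function(scores1, scores2, labels, B = 2000,
                                seed = 1L) {
    if (B < 100) stop("B must be >= 100", call. = FALSE)
    if (is.factor(labels)) labels <- labels == levels(labels)[2L]
    labels <- as.logical(labels)
    keep <- !is.na(scores1) & !is.na(scores2) & !is.na(labels)
    s1 <- scores1[keep]; s2 <- scores2[keep]; y <- labels[keep]
    if (!any(y) || all(y))
        stop("both classes must be present", call. = FALSE)
    posIdx <- which(y); negIdx <- which(!y)
    delta <- .aucRank(s1, y) - .aucRank(s2, y)
    diffs <- .withSeed(seed, vapply(seq_len(B), function(b) {
        idx <- c(sample(posIdx, length(posIdx), replace = TRUE),
                 sample(negIdx, length(negIdx), replace = TRUE))
        .aucRank(s1[idx], y[idx]) - .aucRank(s2[idx], y[idx])
    }, numeric(1L)))
    p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
    list(delta = delta,
         auc1 = .aucRank(s1, y), auc2 = .aucRank(s2, y),
         ci = unname(quantile(diffs, c(0.025, 0.975))),
         p = min(p, 1), B = B, seed = seed)
}
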
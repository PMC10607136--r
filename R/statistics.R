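#' @importFrom stats fisher.test wilcox.test kruskal.test cor.test p.adjust
#'   prcomp quantile complete.cases
NULL

#' Exact Fisher test on a 2x2 seroprevalence table
#'
#' Compares the prevalence of a seropositive call between two groups with
#' Fisher's exact (hypergeometric) test. The two-sided p-value follows the
#' minimum-likelihood convention (sum of point probabilities of all tables
#' with the same margins that are no more probable than the observed one).
#' The reported odds ratio is the unconditional sample odds ratio
#' \code{(a d) / (b c)}; when any cell is zero the Haldane 0.5 continuity
#' correction is applied to every cell and flagged.
#'
#' @param a,b positives and negatives in group 1.
#' @param c,d positives and negatives in group 2.
#' @param alternative \code{"two_sided"} (default), \code{"greater"} or
#'   \code{"less"} (group 1 vs group 2 odds).
#' @return list with \code{p}, \code{odds_ratio} and
#'   \code{haldane_corrected}.
#' @examples
#' fisherExact2x2(6, 119, 1, 167)$p   # ~0.045
#' @export
fisherExact2x2 <- function(a, b, c, d,
                           alternative = c("two_sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    counts <- c(a, b, c, d)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be nonnegative integers", call. = FALSE)
    if (sum(counts) == 0)
        stop("at least one margin must be positive", call. = FALSE)
    tab <- matrix(counts, nrow = 2, byrow = TRUE)
    alt <- c(two_sided = "two.sided", greater = "greater", less = "less")
    p <- fisher.test(tab, alternative = alt[[alternative]])$p.value
    haldane <- any(counts == 0)
    or <- if (haldane)
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    else (a * d) / (b * c)
    list(p = min(max(p, 0), 1), odds_ratio = or, haldane_corrected = haldane)
}

.twoGroupCalls <- function(x, groupBy, levels, antigens) {
    calls <- callMatrix(x)
    cd <- colData(x)
    if (!groupBy %in% colnames(cd))
        stop(sprintf("unknown grouping variable '%s'", groupBy), call. = FALSE)
    gv <- as.character(cd[[groupBy]])
    if (length(levels) != 2L)
        stop("exactly two group levels are required", call. = FALSE)
    keep <- !colSums(is.na(calls)) & gv %in% levels
    calls <- calls[, keep, drop = FALSE]
    gv <- gv[keep]
    for (lv in levels)
        if (!any(gv == lv))
            stop(sprintf("group level '%s' is empty", lv), call. = FALSE)
    if (!is.null(antigens)) {
        miss <- setdiff(antigens, rownames(calls))
        if (length(miss))
            stop(sprintf("unknown antigen id(s): %s",
                         paste(miss, collapse = ", ")), call. = FALSE)
        calls <- calls[antigens, , drop = FALSE]
    }
    list(calls = calls, groups = gv)
}

#' Per-antigen prevalence comparison between two groups
#'
#' For each antigen, tabulates seropositive calls in two groups defined by a
#' metadata variable (clinical group, ANCA serotype, phenotype, organ flag,
#' timepoint, ...), and tests the 2x2 table with [fisherExact2x2()]. Antigens
#' whose prevalence gap reaches \code{minPrevalenceGap} percentage units are
#' flagged for reporting. Samples with missing calls (degenerate) or outside
#' the two levels are excluded per comparison. No multiple-testing
#' adjustment is applied unless \code{bh = TRUE}, which adds
#' Benjamini-Hochberg q-values across the scan.
#'
#' @param x a \linkS4class{SeroExperiment} after [callReactivity()].
#' @param groupBy name of the \code{colData} variable to split on.
#' @param levels character vector of the two level names (group 1, group 2).
#' @param antigens optional antigen subset.
#' @param minPrevalenceGap reporting threshold in percentage units
#'   (default 10).
#' @param bh add BH-adjusted q-values.
#' @return data.frame with one row per antigen: counts \code{a,b,c,d},
#'   per-group prevalences, gap (percentage units), odds ratio, p, flag, and
#'   optionally \code{q}.
#' @export
comparePrevalence <- function(x, groupBy, levels, antigens = NULL,
                              minPrevalenceGap = 10, bh = FALSE) {
    tg <- .twoGroupCalls(x, groupBy, levels, antigens)
    in1 <- tg$groups == levels[1L]
    n1 <- sum(in1); n2 <- sum(!in1)
    a <- as.integer(rowSums(tg$calls[, in1, drop = FALSE]))
    cc <- as.integer(rowSums(tg$calls[, !in1, drop = FALSE]))
    res <- lapply(seq_along(a), function(i)
        fisherExact2x2(a[i], n1 - a[i], cc[i], n2 - cc[i]))
    out <- data.frame(
        antigen_id = rownames(tg$calls),
        group1 = levels[1L], group2 = levels[2L],
        a = unname(a), b = n1 - unname(a),
        c = unname(cc), d = n2 - unname(cc),
        prevalence1 = unname(a) / n1, prevalence2 = unname(cc) / n2,
        gap = 100 * (unname(a) / n1 - unname(cc) / n2),
        odds_ratio = vapply(res, `[[`, numeric(1L), "odds_ratio"),
        p = vapply(res, `[[`, numeric(1L), "p"))
    out$flagged <- abs(out$gap) >= minPrevalenceGap
    if (bh) out$q <- adjustBH(out$p)
    out
}

#' Rank test of autoantibody load between groups
#'
#' Two groups are compared with the two-sided Mann-Whitney-Wilcoxon rank-sum
#' test (exact when group sizes permit and no ties; normal approximation
#' with tie and continuity correction otherwise, the stats-package default);
#' three or more groups with the Kruskal-Wallis test. Missing loads are
#' dropped.
#'
#' @param loads named vector of per-sample loads ([autoantibodyLoad()]).
#' @param groups vector/factor of group membership aligned with
#'   \code{loads} (or named, in which case it is matched by name).
#' @param levels optional subset/order of levels to compare.
#' @return list with \code{p}, \code{method} and named \code{medians}.
#' @export
rankTestLoad <- function(loads, groups, levels = NULL) {
    if (!is.null(names(groups)) && !is.null(names(loads)))
        groups <- groups[names(loads)]
    g <- as.character(groups)
    keep <- !is.na(loads) & !is.na(g)
    if (!is.null(levels)) keep <- keep & g %in% levels
    loads <- loads[keep]; g <- factor(g[keep], levels = unique(g[keep]))
    if (nlevels(g) < 2L)
        stop("need at least two groups with observations", call. = FALSE)
    if (nlevels(g) == 2L) {
        ht <- suppressWarnings(
            wilcox.test(loads[g == levels(g)[1L]], loads[g == levels(g)[2L]]))
        method <- "wilcoxon"
    } else {
        ht <- kruskal.test(loads, g)
        method <- "kruskal-wallis"
    }
    list(p = ht$p.value, method = method,
         medians = tapply(loads, g, median))
}

#' Spearman correlation of load with a clinical covariate
#'
#' Rank correlation (with tie handling) between autoantibody load and a
#' numeric covariate such as age or the BVAS disease-activity score. Pairs
#' with a missing value in either variable are excluded listwise.
#'
#' @param loads named numeric vector of loads.
#' @param covariate numeric vector aligned with \code{loads} (or named).
#' @return list with \code{rho}, \code{p} and \code{n} (pairs used).
#' @export
loadCovariateCorrelation <- function(loads, covariate) {
    if (!is.null(names(covariate)) && !is.null(names(loads)))
        covariate <- covariate[names(loads)]
    keep <- complete.cases(loads, covariate)
    if (sum(keep) < 3L)
        stop("need at least 3 complete pairs", call. = FALSE)
    ht <- suppressWarnings(
        cor.test(as.numeric(loads[keep]), as.numeric(covariate[keep]),
                 method = "spearman"))
    list(rho = unname(ht$estimate), p = ht$p.value, n = sum(keep))
}

#' Select antigens recurrently targeted across samples
#'
#' Implements the carry-over rule of the untargeted screening stage: keep the
#' antigens called reactive in at least \code{minPositiveSamples} samples
#' (e.g. at least 2 of 80), for inclusion in the next, targeted array design.
#'
#' @param x a \linkS4class{SeroExperiment} after [callReactivity()], or a
#'   binary calls matrix (antigens x samples).
#' @param minPositiveSamples minimum number of reactive samples (>= 1).
#' @return Character vector of antigen ids, in array order.
#' @export
selectRecurrentAntigens <- function(x, minPositiveSamples) {
    stopifnot(minPositiveSamples >= 1)
    calls <- if (is(x, "SeroExperiment")) callMatrix(x) else as.matrix(x)
    rownames(calls)[rowSums(calls, na.rm = TRUE) >= minPositiveSamples]
}

#' PCA check for batch and diagnosis effects
#'
#' Principal component analysis of the nMAD-normalized scores (samples as
#' observations), used to check whether sample provenience (site) or
#' diagnosis dominates the data distribution. Missing scores (degenerate
#' samples) are mean-imputed per antigen before the decomposition and the
#' imputed fraction reported.
#'
#' @param x a \linkS4class{SeroExperiment} after [nmadNormalize()].
#' @param nComponents number of components to return (truncated to the
#'   matrix rank, with a warning).
#' @return list with \code{scores} (data.frame of per-sample component
#'   scores plus \code{group} and \code{site}), \code{varianceExplained}
#'   (fractions) and \code{imputedFraction}.
#' @export
pcaBatchCheck <- function(x, nComponents = 2) {
    stopifnot(nrow(x) >= 2L, ncol(x) >= 2L)
    sc <- nmadMatrix(x)
    impFrac <- mean(is.na(sc))
    if (impFrac > 0) {
        rm_ <- rowMeans(sc, na.rm = TRUE)
        idx <- which(is.na(sc), arr.ind = TRUE)
        sc[idx] <- rm_[idx[, 1L]]
    }
    pc <- prcomp(t(sc), center = TRUE, scale. = FALSE)
    k <- min(nComponents, ncol(pc$x))
    if (k < nComponents)
        warning(sprintf("rank limits components to %d", k), call. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    scores <- data.frame(sample_id = colnames(x),
                         pc$x[, seq_len(k), drop = FALSE])
    if (!is.null(colData(x)$group)) scores$group <- colData(x)$group
    if (!is.null(colData(x)$site)) scores$site <- colData(x)$site
    list(scores = scores, varianceExplained = ve[seq_len(k)],
         imputedFraction = impFrac)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values for a vector of p-values from a
#' prevalence scan. Provided as an explicit, optional step: the primary
#' analyses report unadjusted exact p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as \code{p}.
#' @export
adjustBH <- function(p) {
    if (any(!is.finite(p) | p < 0 | p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    p.adjust(p, method = "BH")
}
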
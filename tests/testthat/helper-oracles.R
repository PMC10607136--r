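suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

# Small lognormal cohort container with no structure, for property tests.
randomSE <- function(nAntigens = 20, nSamples = 10, seed = 1) {
    set.seed(seed)
    m <- matrix(rlnorm(nAntigens * nSamples, 5, 0.5), nrow = nAntigens,
                dimnames = list(sprintf("AG%03d", seq_len(nAntigens)),
                                sprintf("S%03d", seq_len(nSamples))))
    SeroExperiment(m)
}

# Independent Fisher oracle: full enumeration over all 2x2 tables with the
# observed margins; two-sided p sums point probabilities <= that of the
# observed table (relative tolerance for floating ties).
fisherEnum <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    pts <- vapply(lo:hi, function(k)
        choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1), numeric(1))
    pobs <- pts[a - lo + 1L]
    sum(pts[pts <= pobs * (1 + 1e-7)])
}

# Independent AUC oracle: direct count of concordant score pairs, ties 1/2.
aucCount <- function(scores, labels) {
    pos <- scores[as.logical(labels)]
    neg <- scores[!as.logical(labels)]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
}

# Independent robust-statistics oracle: sort-based median and MAD.
sortMedian <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}
sortMAD <- function(x) sortMedian(abs(x - sortMedian(x)))

# Independent BH oracle: textbook step-up formula.
bhDirect <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
}

# Binary call matrix with prescribed per-antigen positive counts, embedded in
# a SeroExperiment-shaped plain matrix (antigens x samples).
callsWithCounts <- function(counts, nSamples, seed = 1) {
    set.seed(seed)
    m <- matrix(0L, nrow = length(counts), ncol = nSamples,
                dimnames = list(sprintf("AG%03d", seq_along(counts)),
                                sprintf("S%03d", seq_len(nSamples))))
    for (i in seq_along(counts))
        m[i, sample.int(nSamples, counts[i])] <- 1L
    m
}
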
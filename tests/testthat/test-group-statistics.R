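test_that("fisherExact2x2 agrees with fixed-margin enumeration on small tables", {
    set.seed(19)
    for (i in 1:60) {
        tot <- sample(4:12, 1)
        a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
        c_ <- sample(0:(tot - a - b), 1); d <- tot - a - b - c_
        if (a + b == 0 && c_ + d == 0) next
        expect_equal(fisherExact2x2(a, b, c_, d)$p, fisherEnum(a, b, c_, d),
                     tolerance = 1e-10)
    }
    expect_equal(fisherExact2x2(0, 10, 0, 10)$p, 1)
    expect_error(fisherExact2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("fisherExact2x2 symmetries and odds-ratio conventions hold", {
    r <- fisherExact2x2(6, 119, 1, 167)
    expect_equal(r$odds_ratio, (6 * 167) / (119 * 1))
    expect_false(r$haldane_corrected)
    # swapping rows together with columns leaves p unchanged
    r2 <- fisherExact2x2(167, 1, 119, 6)
    expect_equal(r$p, r2$p, tolerance = 1e-12)
    # group swap inverts the odds ratio
    r3 <- fisherExact2x2(1, 167, 6, 119)
    expect_equal(r3$odds_ratio, 1 / r$odds_ratio)
    expect_equal(r3$p, r$p, tolerance = 1e-12)
    # zero cell triggers the flagged Haldane correction
    rz <- fisherExact2x2(5, 5, 0, 10)
    expect_true(rz$haldane_corrected)
    expect_equal(rz$odds_ratio, (5.5 * 10.5) / (5.5 * 0.5))
    # one-sided alternatives are honoured
    expect_lt(fisherExact2x2(9, 1, 1, 9, alternative = "greater")$p,
              fisherExact2x2(9, 1, 1, 9, alternative = "less")$p)
})

test_that("comparePrevalence recovers a planted group difference", {
    prev <- matrix(0.02, 2, 20, dimnames = list(c("AAV", "HC"), NULL))
    prev["AAV", 7] <- 0.4; prev["HC", 7] <- 0.1
    cfg <- simulationConfig(c(AAV = 120, HC = 120), nAntigens = 20,
                            prevalence = prev, seed = 15)
    se <- callReactivity(simulateCohort(cfg), nFactor = 20)
    res <- comparePrevalence(se, "group", c("AAV", "HC"))
    best <- res$antigen_id[which.min(res$p)]
    expect_identical(best, rownames(se)[7])
    expect_true(res$flagged[7])
    expect_identical(res$a + res$b, rep(120L, 20))

    swapped <- comparePrevalence(se, "group", c("HC", "AAV"))
    expect_equal(swapped$p, res$p, tolerance = 1e-12)
    expect_equal(swapped$odds_ratio, 1 / res$odds_ratio, tolerance = 1e-9)

    expect_error(comparePrevalence(se, "group", c("AAV", "GCA")), "GCA")
    expect_error(comparePrevalence(se, "nope", c("AAV", "HC")), "nope")
})

test_that("identical groups show zero prevalence gaps", {
    calls <- callsWithCounts(c(4, 0, 9), nSamples = 12, seed = 2)
    m <- cbind(calls, calls)
    colnames(m) <- sprintf("S%02d", 1:24)
    md <- DataFrame(group = rep(c("g1", "g2"), each = 12),
                    row.names = colnames(m))
    se <- SeroExperiment(matrix(1, nrow(m), ncol(m), dimnames = dimnames(m)),
                         sampleData = md)
    assay(se, "calls") <- m
    res <- comparePrevalence(se, "group", c("g1", "g2"))
    expect_equal(res$gap, rep(0, 3))
    expect_equal(res$p, rep(1, 3))
})

test_that("rank tests on load follow the exact small-sample references", {
    r <- rankTestLoad(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
    expect_equal(r$p, 1)
    r2 <- rankTestLoad(c(1, 2, 3, 101, 102, 103),
                       rep(c("a", "b"), each = 3))
    expect_equal(r2$p, 0.1)    # smallest attainable exact two-sided p at 3v3
    expect_identical(r2$method, "wilcoxon")
    r3 <- rankTestLoad(c(1, 2, 3, 4, 5, 6, 70, 80, 90),
                       rep(c("a", "b", "c"), each = 3))
    expect_identical(r3$method, "kruskal-wallis")
    expect_error(rankTestLoad(1:5, rep("a", 5)), "two groups")
})

test_that("load rank test direction matches the group medians", {
    set.seed(40)
    loads <- c(rpois(60, 5), rpois(60, 4))
    sex <- rep(c("M", "F"), each = 60)
    r <- rankTestLoad(loads, sex)
    expect_gte(r$medians[["M"]], r$medians[["F"]])
})

test_that("Spearman load-covariate correlation hits the rank extremes", {
    loads <- c(a = 1, b = 4, c = 2, d = 9, e = 6)
    expect_equal(loadCovariateCorrelation(loads, loads)$rho, 1)
    expect_equal(loadCovariateCorrelation(loads, -loads)$rho, -1)
    expect_error(loadCovariateCorrelation(c(1, 2), c(1, 2)), "3 complete")
    # missing pairs are dropped listwise
    cov <- c(2, NA, 4, 1, 7)
    expect_identical(loadCovariateCorrelation(loads, cov)$n, 4L)
    # independent covariate: small correlation at n = 200
    set.seed(11)
    r <- loadCovariateCorrelation(rpois(200, 5), rnorm(200))
    expect_lt(abs(r$rho), 0.2)
})

test_that("recurrent-antigen selection applies the carry-over threshold", {
    counts <- c(rep(3, 25), rep(2, 15), rep(1, 40), rep(0, 40))
    calls <- callsWithCounts(counts, nSamples = 80, seed = 5)
    sel <- selectRecurrentAntigens(calls, minPositiveSamples = 2)
    expect_identical(sel, rownames(calls)[1:40])    # exactly the 40 planted
    expect_identical(length(selectRecurrentAntigens(calls, 3)), 25L)
})

test_that("PCA batch check behaves on degenerate and batch-free data", {
    m <- cbind(s1 = c(1, 5, 2, 8), s2 = c(1, 5, 2, 8), s3 = c(4, 1, 9, 2))
    rownames(m) <- paste0("a", 1:4)
    pc <- pcaBatchCheck(nmadNormalize(SeroExperiment(m)), nComponents = 2)
    expect_equal(as.numeric(pc$scores[1, 2:3]), as.numeric(pc$scores[2, 2:3]))
    # rank-1 matrix: first component carries all variance
    r1 <- outer(c(1, 2, 3, 4), c(1, 2, 4, 8, 16))
    dimnames(r1) <- list(paste0("a", 1:4), paste0("s", 1:5))
    se1 <- SeroExperiment(r1)
    assay(se1, "nmad") <- r1
    expect_warning(pcr <- pcaBatchCheck(se1, nComponents = 6), "rank|components")
    expect_equal(pcr$varianceExplained[1], 1, tolerance = 1e-8)
    # no site effect in the generator -> site explains little of PC1
    cfg <- simulationConfig(c(AAV = 60, HC = 60), nAntigens = 40,
                            siteEffectLogSd = 0, seed = 23)
    se <- nmadNormalize(simulateCohort(cfg))
    pc2 <- pcaBatchCheck(se, nComponents = 2)
    fit <- summary(lm(pc2$scores$PC1 ~ pc2$scores$site))
    expect_lt(fit$r.squared, 0.10)
})

test_that("BH adjustment matches the direct step-up formula", {
    expect_equal(adjustBH(0.04), 0.04)
    expect_equal(adjustBH(rep(0.2, 6)), rep(0.2, 6))
    set.seed(9)
    p <- runif(50)
    q <- adjustBH(p)
    expect_equal(q, bhDirect(p))
    expect_true(all(q >= p) && all(q <= 1))
    expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
})
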
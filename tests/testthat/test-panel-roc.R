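.panelSE <- function(callRows, nmadRows = NULL) {
    m <- matrix(1, nrow(callRows), ncol(callRows), dimnames = dimnames(callRows))
    se <- SeroExperiment(m)
    assay(se, "calls") <- callRows
    if (!is.null(nmadRows)) assay(se, "nmad") <- nmadRows
    se
}

test_that("panel binary rules implement k-of-n, OR and AND", {
    calls <- rbind(A = c(1L, 1L, 0L, 0L), B = c(0L, 1L, 0L, 1L),
                   C = c(0L, 1L, 0L, 0L))
    colnames(calls) <- paste0("s", 1:4)
    se <- .panelSE(calls)
    p1 <- panelCall(se, AntibodyPanel(c("A", "B", "C"), k = 1))
    p2 <- panelCall(se, AntibodyPanel(c("A", "B", "C"), k = 2))
    p3 <- panelCall(se, AntibodyPanel(c("A", "B", "C"), k = 3))
    expect_identical(unname(p1), as.integer(colSums(calls) >= 1)) # OR
    expect_identical(unname(p3), as.integer(colSums(calls) == 3)) # AND
    expect_identical(unname(p2), c(0L, 1L, 0L, 0L))
    expect_error(panelCall(se, AntibodyPanel(c("A", "Z"), k = 1)), "Z")
    expect_error(AntibodyPanel(c("A", "B"), k = 3), "panel size")
})

test_that("panel scores combine members as specified", {
    calls <- rbind(A = c(1L, 1L), B = c(1L, 0L), C = c(0L, 0L))
    nmad <- rbind(A = c(2, -1), B = c(3, 0.5), C = c(-1, 0))
    colnames(calls) <- colnames(nmad) <- c("s1", "s2")
    se <- .panelSE(calls, nmad)
    expect_equal(unname(panelScore(se, AntibodyPanel(c("A", "B", "C"), 1,
                                                     "sum_nmad"))),
                 c(4, -0.5))
    expect_equal(unname(panelScore(se, AntibodyPanel(c("A", "B", "C"), 1,
                                                     "max_nmad"))),
                 c(3, 0.5))
    expect_equal(unname(panelScore(se, AntibodyPanel(c("A", "B", "C"), 1,
                                                     "count_positive"))),
                 c(2, 1))
    # order invariance
    expect_equal(panelScore(se, AntibodyPanel(c("C", "A", "B"), 1, "sum_nmad")),
                 panelScore(se, AntibodyPanel(c("A", "B", "C"), 1, "sum_nmad")))
})

test_that("ROC curve hits the separability extremes and sign reversal", {
    scores <- c(1, 2, 3, 10, 11, 12)
    labels <- c(0, 0, 0, 1, 1, 1)
    roc <- rocCurve(scores, labels)
    expect_equal(auc(roc), 1)
    op <- operatingPoint(roc, "youden")
    expect_equal(op$sensitivity, 1); expect_equal(op$specificity, 1)
    expect_equal(auc(rocCurve(-scores, labels)), 0)
    # uninformative constant score: boundary sens + spec = 1
    rocU <- rocCurve(rep(2, 6), labels)
    opU <- operatingPoint(rocU, "youden")
    expect_equal(opU$sensitivity + opU$specificity, 1)
    expect_error(operatingPoint(roc, "fixed_specificity", value = 2),
                 "unattainable")
    expect_error(rocCurve(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoidal AUC equals the rank oracle and pROC on random data", {
    skip_if_not_installed("pROC")
    set.seed(44)
    for (i in 1:25) {
        n <- sample(8:40, 1)
        scores <- sample(1:10, n, replace = TRUE)   # plenty of ties
        labels <- rbinom(n, 1, 0.5)
        if (sum(labels) == 0 || sum(labels) == n) next
        a1 <- auc(rocCurve(scores, labels))
        expect_equal(a1, aucCount(scores, labels), tolerance = 1e-12)
        a2 <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
        expect_equal(a1, a2, tolerance = 1e-10)
    }
})

test_that("AUC is invariant under strictly increasing score transforms", {
    set.seed(3)
    scores <- rnorm(60); labels <- rbinom(60, 1, 0.4)
    a <- auc(rocCurve(scores, labels))
    expect_equal(auc(rocCurve(exp(scores), labels)), a, tolerance = 1e-12)
    expect_equal(auc(rocCurve(rank(scores), labels)), a, tolerance = 1e-12)
    expect_equal(auc(rocCurve(-scores, labels)), 1 - a, tolerance = 1e-12)
})

test_that("null scores give chance-level AUC at n = 2000", {
    set.seed(17)
    scores <- rnorm(2000); labels <- rbinom(2000, 1, 0.5)
    expect_true(abs(auc(rocCurve(scores, labels)) - 0.5) < 0.05)
})

test_that("fixed-specificity operating points respect the constraint", {
    set.seed(5)
    scores <- c(rnorm(50), rnorm(50, 1.5)); labels <- rep(0:1, each = 50)
    roc <- rocCurve(scores, labels)
    op <- operatingPoint(roc, "fixed_specificity", value = 0.9)
    expect_gte(op$specificity, 0.9)
    # no point with specificity >= 0.9 has higher sensitivity
    ok <- roc@specificity >= 0.9
    expect_equal(op$sensitivity, max(roc@sensitivity[ok]))
})

test_that("paired bootstrap is deterministic and calibrated at the extremes", {
    set.seed(8)
    scores <- c(rnorm(40), rnorm(40, 2)); labels <- rep(0:1, each = 40)
    same <- bootstrapCompareAUC(scores, scores, labels, B = 200, seed = 4)
    expect_equal(same$delta, 0)
    expect_equal(same$p, 1)
    expect_error(bootstrapCompareAUC(scores, scores, labels, B = 10), ">= 100")
})

test_that("an informative score beats a random one with CI excluding zero", {
    set.seed(12)
    n <- 400
    labels <- rep(0:1, each = n / 2)
    good <- rnorm(n) + 1.5 * labels
    noise <- rnorm(n)
    r <- bootstrapCompareAUC(good, noise, labels, B = 400, seed = 2)
    expect_gt(r$ci[1], 0)
    expect_lt(r$p, 0.05)
    # determinism under a fixed seed
    r2 <- bootstrapCompareAUC(good, noise, labels, B = 400, seed = 2)
    expect_identical(r, r2)
})
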
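ctTable <- function(ctrlTarget, testTarget, ctrlRef = 20, testRef = 20,
                    target = "GENE", reference = "REF",
                    groups = c("control", "treated")) {
    n <- length(ctrlTarget)
    data.frame(
        sample_id = rep(c(paste0("c", 1:n), paste0("t", 1:n)), 2),
        group = rep(rep(groups, each = n), 2),
        target = rep(c(target, reference), each = 2 * n),
        replicate = 1L,
        ct = c(ctrlTarget, testTarget, rep(ctrlRef, n), rep(testRef, n)))
}

test_that("2^-ddCt recovers the hand-computed Livak folds", {
    # equal delta-Ct means: fold 1
    ct <- ctTable(c(24.9, 25.0, 25.1), c(24.9, 25.0, 25.1))
    r <- deltaDeltaCt(ct, "GENE", "REF", "control", "treated")
    expect_equal(r$ddct, 0, tolerance = 1e-12)
    expect_equal(r$fold, 1, tolerance = 1e-12)
    # ddCt +1 -> fold 0.5 ; ddCt -1 -> fold 2
    up <- deltaDeltaCt(ctTable(c(24.9, 25, 25.1), c(25.9, 26, 26.1)),
                       "GENE", "REF", "control", "treated")
    expect_equal(up$ddct, 1, tolerance = 1e-12)
    expect_equal(up$fold, 0.5, tolerance = 1e-12)
    dn <- deltaDeltaCt(ctTable(c(24.9, 25, 25.1), c(23.9, 24, 24.1)),
                       "GENE", "REF", "control", "treated")
    expect_equal(dn$fold, 2, tolerance = 1e-12)
    # Livak worked example: test target Ct 26.585 vs control 25, ref 20
    lv <- deltaDeltaCt(ctTable(rep(25, 3) + c(-.01, 0, .01),
                               rep(26.585, 3) + c(-.01, 0, .01)),
                       "GENE", "REF", "control", "treated")
    expect_equal(lv$ddct, 1.585, tolerance = 1e-9)
    expect_equal(lv$fold, 2^-1.585, tolerance = 1e-9)
    expect_equal(lv$fold, 1 / 3, tolerance = 1e-4)
    # pooled SE of the ddCt and asymmetric fold interval
    sdg <- stats::sd(c(-.01, 0, .01)) / sqrt(3)
    expect_equal(lv$seDdct, sqrt(2) * sdg, tolerance = 1e-9)
    expect_equal(unname(lv$foldInterval),
                 2^(-(1.585 + c(1, -1) * lv$seDdct)), tolerance = 1e-9)
})

test_that("plate offsets cancel and group swap inverts the fold exactly", {
    base <- ctTable(c(24.8, 25.1, 25.06), c(23.2, 23.9, 23.75),
                    ctrlRef = 20.3, testRef = 19.8)
    r0 <- deltaDeltaCt(base, "GENE", "REF", "control", "treated")
    shifted <- base; shifted$ct <- shifted$ct + 3.7
    r1 <- deltaDeltaCt(shifted, "GENE", "REF", "control", "treated")
    expect_equal(r0$fold, r1$fold, tolerance = 1e-12)
    expect_equal(r0$pRaw, r1$pRaw, tolerance = 1e-12)
    swap <- deltaDeltaCt(base, "GENE", "REF", "treated", "control")
    expect_equal(swap$fold, 1 / r0$fold, tolerance = 1e-12)
    # control vs itself is identically 1
    self <- deltaDeltaCt(base, "GENE", "REF", "control", "control")
    expect_equal(self$fold, 1, tolerance = 1e-12)
})

test_that("missing assays, unmatched groups and short groups raise explicit errors", {
    ct <- ctTable(c(25, 25.1, 24.9), c(24, 24.1, 23.9))
    expect_error(deltaDeltaCt(ct, "GENE", "IPO8", "control", "treated"),
                 "missing reference assay")
    expect_error(deltaDeltaCt(ct, "GENE", "REF", "control", "knockout"),
                 "not present")
    one <- ct[ct$sample_id %in% c("c1", "t1", "t2"), ]
    expect_error(deltaDeltaCt(one, "GENE", "REF", "control", "treated"),
                 "at least two delta-Ct")
})

test_that("technical replicates are averaged within sample before group statistics", {
    # two samples per group, three technical replicates each; jitter the
    # technical replicates asymmetrically so averaging matters
    mk <- function(grp, s, target, ct3)
        data.frame(sample_id = paste0(grp, s), group = grp,
                   target = target, replicate = 1:3, ct = ct3)
    ct <- rbind(
        mk("control", 1, "GENE", c(25.0, 25.3, 24.7)),
        mk("control", 2, "GENE", c(25.2, 25.2, 25.2)),
        mk("control", 1, "REF", c(20, 20, 20)),
        mk("control", 2, "REF", c(20.1, 20.1, 20.1)),
        mk("treated", 1, "GENE", c(24.0, 24.0, 24.0)),
        mk("treated", 2, "GENE", c(24.4, 23.8, 24.0)),
        mk("treated", 1, "REF", c(20, 20, 20)),
        mk("treated", 2, "REF", c(20.05, 20.05, 20.05)))
    r <- deltaDeltaCt(ct, "GENE", "REF", "control", "treated")
    # sample-level dCt: control (5.0, 5.1); treated (4.0, 4.0166...)
    expect_equal(unname(r$nUnits), c(2, 2))
    expect_equal(unname(r$deltaCtMean[["control"]]), 5.05, tolerance = 1e-9)
    expect_equal(r$ddct, mean(c(4, 72.2 / 3 - 20.05)) - 5.05,
                 tolerance = 1e-9)
})

test_that("Welch p-values match a direct t-distribution evaluation and Bonferroni caps at 1", {
    withr::with_seed(43, {
        for (rep in 1:20) {
            x <- stats::rnorm(5, 1); y <- stats::rnorm(7)
            got <- ttestBonferroni(list(ctrl = y, trt = x), m = 3)
            # direct Welch CDF oracle
            vx <- stats::var(x) / 5; vy <- stats::var(y) / 7
            tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
            df <- (vx + vy)^2 / (vx^2 / 4 + vy^2 / 6)
            pOracle <- 2 * stats::pt(-abs(tstat), df)
            expect_equal(got$pRaw, pOracle, tolerance = 1e-10)
            expect_equal(got$pAdj, min(1, 3 * pOracle), tolerance = 1e-10)
        }
    })
    same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
    expect_equal(ttestBonferroni(same)$pRaw, 1)
    expect_warning(ttestBonferroni(list(a = c(2, 2), b = c(2, 2))),
                   "zero variance")
    expect_equal(ttestBonferroni(list(a = c(1, 2), b = c(5, 6)), m = 1)$pAdj,
                 ttestBonferroni(list(a = c(1, 2), b = c(5, 6)), m = 1)$pRaw)
})

test_that("3C quantification reports doubled interaction for ddCt = -1 against the ERCC3 control", {
    n <- 3
    ct <- data.frame(
        sample_id = rep(c(paste0("c", 1:n), paste0("d", 1:n)), 2),
        group = rep(rep(c("control", "deletion"), each = n), 2),
        target = rep(c("MSX1_PIR_junction", "ERCC3"), each = 2 * n),
        replicate = 1L,
        ct = c(27.9, 28, 28.1, 26.9, 27, 27.1, rep(24, 2 * n)))
    r <- quantify3c(ct, "MSX1_PIR_junction",
                    controlGroup = "control", testGroup = "deletion")
    expect_equal(r$reference, "ERCC3")
    expect_equal(r$ddct, -1, tolerance = 1e-12)
    expect_equal(r$fold, 2, tolerance = 1e-12)   # interaction doubled
    self <- quantify3c(ct, "MSX1_PIR_junction",
                       controlGroup = "control", testGroup = "control")
    expect_equal(self$fold, 1, tolerance = 1e-12)
})

test_that("planted qPCR folds are recovered within three standard errors", {
    inside <- vapply(1:20, function(i) {
        sim <- simulatePirData(smallConfig(seed = 1000 + i))
        r <- deltaDeltaCt(sim$ct, "MSX1", "IPO8", "control", "deletion")
        abs(r$ddct - (-1)) <= 3 * r$seDdct
    }, logical(1))
    expect_gte(sum(inside), 19)
})
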
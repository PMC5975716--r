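randomProps <- function(n, types = c("A", "B", "C")) {
    g <- matrix(rgamma(n * length(types), 1), n)
    p <- g / rowSums(g)
    dimnames(p) <- list(paste0("m", seq_len(n)), types)
    p
}

test_that("performanceStats matches hand-computed R2/RMSE", {
    truth <- cbind(A = c(0.2, 0.5, 0.8), B = c(0.8, 0.5, 0.2))
    rownames(truth) <- paste0("m", 1:3)
    est <- truth
    ps <- performanceStats(est, truth)$performance
    expect_equal(ps$r2[1:2], c(1, 1))
    expect_equal(ps$rmse, rep(0, 3))

    # constant +0.01 shift: RMSE 1 percentage point, R2 still 1
    ps2 <- performanceStats(pmin(truth + 0.01, 1), truth)$performance
    expect_equal(ps2$rmse[1:2], c(1, 1), tolerance = 1e-10)
    expect_equal(ps2$r2[1:2], c(1, 1))

    # arbitrary 3-sample table vs direct formulas
    est3 <- cbind(A = c(0.25, 0.45, 0.9), B = c(0.75, 0.55, 0.1))
    rownames(est3) <- rownames(truth)
    ps3 <- performanceStats(est3, truth)$performance
    expect_equal(ps3$r2[1], cor(est3[, 1], truth[, 1])^2)
    expect_equal(ps3$rmse[1],
                 100 * sqrt(mean((est3[, 1] - truth[, 1])^2)))
    # alternative R2 definition
    alt <- performanceStats(est3, truth, r2 = "one_minus_ss")$performance
    expect_equal(alt$r2[1],
                 1 - sum((est3[, 1] - truth[, 1])^2) /
                     sum((truth[, 1] - mean(truth[, 1]))^2))
})

test_that("error tables are exact differences in percentage points", {
    set.seed(3)
    truth <- randomProps(5)
    est <- randomProps(5)
    ps <- performanceStats(est, truth)
    e <- ps$errors
    i <- which(e$sample_id == "m2" & e$cell_type == "B")
    expect_equal(e$signed_error[i], 100 * (est["m2", "B"] - truth["m2", "B"]))
    expect_equal(e$abs_error, abs(e$signed_error))
    # mean signed <= mean absolute per cell type
    for (k in unique(e$cell_type)) {
        sel <- e$cell_type == k
        expect_lte(mean(e$signed_error[sel]), mean(e$abs_error[sel]))
    }
})

test_that("performance is invariant under sample and column reordering", {
    set.seed(4)
    truth <- randomProps(6)
    est <- randomProps(6)
    ps1 <- performanceStats(est, truth)$performance
    ps2 <- performanceStats(est[c(3, 1, 6, 2, 5, 4), c(2, 3, 1)],
                            truth)$performance
    expect_equal(ps1, ps2)
    expect_error(performanceStats(est[1:3, ], truth), "sample ids")
})

test_that("Bland-Altman limits follow the mean +/- 1.96 SD formula", {
    truth <- cbind(A = c(0.5, 0.5), B = c(0.5, 0.5))
    rownames(truth) <- c("m1", "m2")
    est <- cbind(A = c(0.51, 0.49), B = c(0.505, 0.505))
    rownames(est) <- rownames(truth)
    ba <- blandAltman(est, truth)
    # A: differences +1/-1 pp -> mean 0, SD sqrt(2)
    expect_equal(ba$mean_diff[ba$cell_type == "A"], 0)
    expect_equal(ba$upper[ba$cell_type == "A"], 1.96 * sqrt(2))
    # B: constant +0.5 pp bias -> zero-width limits
    expect_equal(ba$mean_diff[ba$cell_type == "B"], 0.5)
    expect_equal(ba$upper[ba$cell_type == "B"] -
                 ba$lower[ba$cell_type == "B"], 0)
    # est = truth -> all zero
    ba0 <- blandAltman(truth, truth)
    expect_true(all(ba0$mean_diff == 0 & ba0$lower == 0 & ba0$upper == 0))
    expect_error(blandAltman(est[1, , drop = FALSE],
                             truth[1, , drop = FALSE]), "single sample")
})

test_that("paired t-test matches the textbook statistic and is symmetric", {
    truth <- cbind(A = c(0.10, 0.20, 0.30))
    rownames(truth) <- paste0("m", 1:3)
    est <- cbind(A = truth[, 1] + c(0.01, 0.02, 0.03))
    rownames(est) <- rownames(truth)
    pt <- pairedT(est, truth)
    # differences 1,2,3 pp: mean 2, sd 1, t = 2*sqrt(3)
    expect_equal(pt$t, 2 * sqrt(3), tolerance = 1e-12)
    expect_equal(pt$mean_diff, 2)
    rev <- pairedT(truth, est)
    expect_equal(rev$t, -pt$t)
    expect_equal(rev$p, pt$p)
    # est = truth: t 0, p 1
    pt0 <- pairedT(truth, truth)
    expect_equal(pt0$t, 0)
    expect_equal(pt0$p, 1)
    # exact bias: zero-variance nonzero-mean differences
    ptb <- pairedT(truth + 0.05, truth)
    expect_true(ptb$exact_bias)
    expect_equal(ptb$t, Inf)
    expect_equal(ptb$p, 0)
    # global scope pools everything
    set.seed(5)
    tr <- randomProps(4); es <- randomProps(4)
    g <- pairedT(es, tr, scope = "global")
    d <- 100 * as.numeric(es[rownames(tr), colnames(tr)] - tr)
    expect_equal(g$t, unname(t.test(d)$statistic))
})

test_that("Bartlett test matches the closed-form statistic", {
    set.seed(6)
    groups <- list(a = rnorm(10, sd = 1), b = rnorm(10, sd = 2),
                   c = rnorm(12, sd = 0.5))
    bt <- bartlettAcrossMethods(groups)
    expect_equal(bt$statistic, oracleBartlett(groups), tolerance = 1e-10)
    expect_equal(bt$p, pchisq(bt$statistic, 2, lower.tail = FALSE))
    # permuting groups leaves the statistic unchanged
    expect_equal(bartlettAcrossMethods(rev(groups))$statistic,
                 bt$statistic)
    # identical groups -> statistic ~ 0
    same <- list(groups$a, groups$a)
    expect_lt(bartlettAcrossMethods(same)$statistic, 1e-10)
    expect_error(bartlettAcrossMethods(list(c(1, 1, 1), rnorm(5))),
                 "zero-variance")
})

test_that("cell ratios follow their definitions and guard zero division", {
    p <- matrix(rep(1 / 6, 6), 1, dimnames = list("m1",
                canonicalCellTypes()))
    r <- cellRatios(p)
    expect_equal(r$cd4t_cd8t, 1)
    expect_equal(r$cd8t_bcell, 1)
    expect_equal(r$cd8t_mono_nk, 2)
    expect_equal(r$nlr, (1 / 6) / (4 / 6))
    # Neu 0.5 vs lymphocytes summing 0.5 -> NLR 1
    p2 <- matrix(c(0.5, 0.1, 0.15, 0.15, 0.1, 0.1), 1,
                 dimnames = list("m1", canonicalCellTypes()))
    expect_equal(cellRatios(p2)$nlr, 1)
    # NK = 0: only the NK-denominator ratio is flagged missing
    p3 <- p2; p3[1, "NK"] <- 0
    r3 <- cellRatios(p3)
    expect_true(is.na(r3$cd8t_mono_nk))
    expect_false(anyNA(r3[c("nlr", "cd4t_cd8t", "cd8t_bcell")]))
    expect_error(cellRatios(p2[, -6, drop = FALSE]), "missing canonical")
})

test_that("library context chi-squared matches the textbook formula", {
    tab <- rbind(lib1 = c(10, 20), lib2 = c(20, 10))
    got <- libraryContextChisq(tab)
    expect_equal(got$statistic, oracleChisq(tab), tolerance = 1e-12)
    expect_equal(got$df, 1)
    # scaling counts x10 scales the statistic x10
    expect_equal(libraryContextChisq(tab * 10)$statistic,
                 10 * got$statistic, tolerance = 1e-10)
    # identical compositions -> statistic 0, p 1
    same <- rbind(c(30, 70), c(30, 70))
    expect_equal(libraryContextChisq(same)$statistic, 0)
    expect_equal(libraryContextChisq(same)$p, 1)
    expect_error(libraryContextChisq(rbind(c(0, 0), c(1, 2))),
                 "degenerate")
})

test_that("libraryContextCounts tabulates annotations per library", {
    ann <- data.frame(
        probe_id = sprintf("cg%02d", 1:6),
        island_context = c("island", "shore", "open_sea", "open_sea",
                           "shelf", "island"))
    l1 <- ProbeLibrary(c("cg01", "cg03", "cg04"), rep("A", 3), c(1, 2, 3))
    l2 <- ProbeLibrary(c("cg02", "cg05", "cg06"), rep("B", 3), c(1, 2, 3))
    cnt <- libraryContextCounts(list(one = l1, two = l2), ann)
    expect_equal(cnt["one", "open_sea"], 2)
    expect_equal(cnt["two", "island"], 1)
    expect_equal(rowSums(cnt), c(one = 3, two = 3))
})

test_that("statistics match direct formulas on many random tables", {
    set.seed(7)
    for (i in 1:25) {
        n <- sample(3:8, 1)
        truth <- randomProps(n)
        est <- randomProps(n)
        d <- 100 * as.numeric(est - truth)
        expect_equal(pairedT(est, truth, scope = "global")$t,
                     mean(d) / (sd(d) / sqrt(length(d))),
                     tolerance = 1e-8)
        groups <- list(rnorm(sample(5:10, 1)), rnorm(sample(5:10, 1)),
                       rnorm(sample(5:10, 1), sd = 2))
        expect_equal(bartlettAcrossMethods(groups)$statistic,
                     oracleBartlett(groups), tolerance = 1e-8)
        tab <- matrix(rpois(6, 20) + 1, 2, 3)
        expect_equal(libraryContextChisq(tab)$statistic,
                     oracleChisq(tab), tolerance = 1e-8)
        ba <- blandAltman(est, truth)
        k <- colnames(truth)[1]
        dk <- 100 * (est[, k] - truth[, k])
        expect_equal(ba$upper[ba$cell_type == k],
                     mean(dk) + 1.96 * sd(dk), tolerance = 1e-8)
    }
})
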
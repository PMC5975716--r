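# small training scene reused by the IDOL tests
idolScene <- function(seed = 41, nProbes = 300, nDmr = 4, phi = 500,
                      nMix = 6) {
    sim <- smallSim(seed = seed, nProbes = nProbes, nDmrPerType = nDmr,
                    phi = phi, nMix = nMix)
    ts <- computeTStats(sim$ref)
    sim$tstats <- ts
    sim
}

test_that("scoreLibrary reports perfect scores for perfect estimates", {
    sc <- idolScene(phi = Inf)
    lib <- plantedLibrary(sc$profiles)
    perf <- scoreLibrary(lib, sc$ref, sc$mixtures, sc$truth)
    expect_true(all(perf$rmse < 1e-4))
    expect_true(all(perf$r2[perf$cell_type != "mean"] > 1 - 1e-6))
    expect_error(
        scoreLibrary(lib, sc$ref, sc$mixtures[, 1, drop = FALSE],
                     sc$truth[1, , drop = FALSE]),
        "fewer than 2")
})

test_that("leave-one-out deltas equal brute-force rescoring", {
    sc <- idolScene(seed = 43, nProbes = 120, nDmr = 2, nMix = 4)
    pool <- buildCandidatePool(sc$tstats, L = 2)
    lib <- pool[seq_len(min(6L, length(pool)))]
    deltas <- leaveOneOut(lib, sc$ref, sc$mixtures, sc$truth)
    full <- scoreLibrary(lib, sc$ref, sc$mixtures, sc$truth)
    fullRMSE <- full$rmse[full$cell_type == "mean"]
    for (j in seq_along(deltas)) {
        red <- scoreLibrary(lib[-j], sc$ref, sc$mixtures, sc$truth)
        expect_equal(deltas[[j]],
                     fullRMSE - red$rmse[red$cell_type == "mean"],
                     tolerance = 1e-12)
    }
    expect_error(leaveOneOut(lib[1], sc$ref, sc$mixtures, sc$truth),
                 ">= 2")
})

test_that("duplicated-information probes have near-zero contributions", {
    sc <- idolScene(seed = 44, phi = Inf, nProbes = 200, nDmr = 3)
    lib <- plantedLibrary(sc$profiles)
    # duplicate every probe's information by pairing probes with identical
    # latent profiles: score a library twice as deep, then check a pair
    deltas <- leaveOneOut(lib, sc$ref, sc$mixtures, sc$truth)
    expect_lt(max(abs(deltas)), 1e-4)  # noiseless + redundant library
})

test_that("an anti-informative decoy probe gets a positive delta", {
    sc <- idolScene(seed = 45, phi = Inf, nProbes = 200, nDmr = 3)
    lib <- plantedLibrary(sc$profiles)
    # corrupt one library probe in the mixtures: its mixture signal no
    # longer matches the reference signature
    mix <- sc$mixtures
    bad <- probeIds(lib)[1]
    mix[bad, ] <- pmin(1, pmax(0, 1 - mix[bad, ]))
    deltas <- leaveOneOut(lib, sc$ref, mix, sc$truth)
    expect_gt(deltas[[bad]], 0)
    expect_gt(deltas[[bad]], max(deltas[names(deltas) != bad]))
})

test_that("weight updates are multiplicative, capped and floored", {
    cfg <- idolConfig(weightUp = 1.2, weightDown = 0.8, minWeight = 0.05)
    w <- c(a = 0.9, b = 0.5, c = 0.05, d = 1, e = 0.3)
    deltas <- c(a = -1, b = 0, c = 2, e = 0.1)   # d unsampled
    w2 <- updateWeights(w, deltas, cfg)
    expect_equal(w2[["a"]], 1)                    # 0.9*1.2 capped at 1
    expect_equal(w2[["b"]], 0.5)                  # delta 0: unchanged
    expect_equal(w2[["c"]], 0.05)                 # floored at minWeight
    expect_equal(w2[["d"]], 1)                    # unsampled: unchanged
    expect_equal(w2[["e"]], 0.3 * 0.8)
    expect_equal(updateWeights(w, c(a = 0, b = 0), cfg), w)
    expect_error(updateWeights(w, c(zz = 1), cfg), "weights")
})

test_that("idolOptimize is seed-deterministic and tracks a monotone best", {
    sc <- idolScene(seed = 46, nProbes = 150, nDmr = 2, nMix = 4)
    pool <- buildCandidatePool(sc$tstats, L = 4)
    cfg <- idolConfig(iterations = 12, seed = 7)
    s1 <- idolOptimize(pool, sc$ref, sc$mixtures, sc$truth, 8, cfg)
    s2 <- idolOptimize(pool, sc$ref, sc$mixtures, sc$truth, 8, cfg)
    expect_identical(idolHistory(s1), idolHistory(s2))
    expect_identical(libraryEntries(bestLibrary(s1)),
                     libraryEntries(bestLibrary(s2)))
    expect_identical(idolWeights(s1), idolWeights(s2))
    h <- idolHistory(s1)
    best <- tapply(h$best_mean_rmse, h$iteration, unique)
    expect_true(all(diff(best) <= 0))
    expect_true(all(idolWeights(s1) >= cfg$minWeight &
                    idolWeights(s1) <= 1))
    # best-so-far never exceeds any sampled library's score
    expect_lte(bestScore(s1)[["mean_rmse"]], min(h$mean_rmse))
})

test_that("a single iteration returns the single sampled library", {
    sc <- idolScene(seed = 47, nProbes = 150, nDmr = 2, nMix = 4)
    pool <- buildCandidatePool(sc$tstats, L = 4)
    cfg <- idolConfig(iterations = 1, seed = 3)
    st <- idolOptimize(pool, sc$ref, sc$mixtures, sc$truth, 6, cfg)
    h <- idolHistory(st)
    expect_equal(unique(h$iteration), 1L)
    expect_equal(bestScore(st)[["mean_rmse"]], unique(h$mean_rmse))
    perf <- scoreLibrary(bestLibrary(st), sc$ref, sc$mixtures, sc$truth)
    expect_equal(perf$rmse[perf$cell_type == "mean"],
                 bestScore(st)[["mean_rmse"]], tolerance = 1e-12)
    expect_error(
        idolOptimize(pool, sc$ref, sc$mixtures, sc$truth,
                     length(pool), cfg), "smaller than")
})

test_that("uniform random search never beats the exhaustive optimum", {
    sc <- idolScene(seed = 48, nProbes = 100, nDmr = 1, nMix = 4)
    ts <- sc$tstats
    # pool of 8: one hyper probe per cell type would be ideal; decoys mixed
    pool <- buildCandidatePool(ts, L = 2)[1:8]
    subsets <- utils::combn(8, 4)
    exhaustive <- apply(subsets, 2, function(idx) {
        p <- scoreLibrary(pool[idx], sc$ref, sc$mixtures, sc$truth)
        p$rmse[p$cell_type == "mean"]
    })
    cfg <- idolConfig(iterations = 15, seed = 5, weightUp = 1,
                      weightDown = 1)  # uniform search reduction
    st <- idolOptimize(pool, sc$ref, sc$mixtures, sc$truth, 4, cfg)
    expect_gte(bestScore(st)[["mean_rmse"]], min(exhaustive) - 1e-12)
})

test_that("size sweep picks the plateau of the planted signal", {
    sc <- idolScene(seed = 49, nProbes = 300, nDmr = 2, phi = 200,
                    nMix = 6)
    # 24 planted DMRs; pool twice as deep, padded with noise probes
    pool <- buildCandidatePool(sc$tstats, L = 8)
    cfg <- idolConfig(sizes = c(4, 24, 40), iterations = 25, seed = 11,
                      plateauTolerance = 0.1)
    sw <- idolSizeSweep(pool, sc$ref, sc$mixtures, sc$truth, cfg)
    expect_equal(nrow(sw$summary), 3L)
    expect_equal(length(bestLibrary(sw$states[["24"]])), 24L)
    # a 4-probe library cannot cover 6 cell types: clearly worse
    rmse <- setNames(sw$summary$mean_rmse, sw$summary$size)
    expect_gt(rmse[["4"]], rmse[["24"]])
    expect_true(sw$chosenSize %in% c(24, 40))
    # single candidate size: chosen trivially
    cfg1 <- idolConfig(sizes = 10, iterations = 3, seed = 2)
    sw1 <- idolSizeSweep(pool, sc$ref, sc$mixtures, sc$truth, cfg1)
    expect_equal(sw1$chosenSize, 10)
    expect_error(idolSizeSweep(pool, sc$ref, sc$mixtures, sc$truth,
                               idolConfig(sizes = 10000, iterations = 1)),
                 "smaller than")
})

test_that("restrictToProbes filters the pool to a whitelist", {
    sc <- idolScene(seed = 50, nProbes = 120, nDmr = 2, nMix = 4)
    pool <- buildCandidatePool(sc$tstats, L = 2)
    keep <- probeIds(pool)[seq(1, length(pool), by = 2)]
    sub <- restrictToProbes(pool, keep)
    expect_setequal(probeIds(sub), keep)
    expect_error(restrictToProbes(pool, "cg_nope"), "whitelist")
})
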
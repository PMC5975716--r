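# fixtures shared across test files; everything is generated in code

# tiny deterministic reference: 2 cell types, hand-set betas
tinyReference <- function() {
    b <- matrix(c(
        # s1(A) s2(A) s3(B) s4(B)
        0.80, 0.90, 0.10, 0.20,   # cg01: hyper in A
        0.10, 0.20, 0.80, 0.90,   # cg02: hyper in B
        0.50, 0.50, 0.50, 0.50),  # cg03: uninformative
        nrow = 3, byrow = TRUE,
        dimnames = list(c("cg01", "cg02", "cg03"),
                        c("s1", "s2", "s3", "s4")))
    ReferenceSet(b, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
}

# small end-to-end simulation shared by heavier tests
smallSim <- function(seed = 101, nProbes = 600, nDmrPerType = 15,
                     phi = 200, nMix = 6) {
    cfg <- simConfig(nProbes = nProbes, nDmrPerType = nDmrPerType,
                     delta = 0.5, phi = phi, seed = seed)
    sim <- simulateReference(cfg)
    truth <- rbind(dirichletDesign("A", nMix, seed = seed + 1),
                   dirichletDesign("B", nMix, seed = seed + 2))
    mix <- simulateMixtures(sim$profiles, truth, phi = phi,
                            seed = seed + 3)
    list(ref = sim$reference, profiles = sim$profiles, truth = truth,
         mixtures = mix, cfg = cfg)
}

# independent textbook pooled-variance two-sample t
oracleT <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# independent Bartlett statistic (closed form)
oracleBartlett <- function(groups) {
    k <- length(groups)
    ni <- vapply(groups, length, 1L)
    vi <- vapply(groups, var, 1)
    N <- sum(ni)
    sp2 <- sum((ni - 1) * vi) / (N - k)
    num <- (N - k) * log(sp2) - sum((ni - 1) * log(vi))
    den <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
    num / den
}

# independent Pearson chi-squared statistic for a counts table
oracleChisq <- function(tab) {
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - exp)^2 / exp)
}
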
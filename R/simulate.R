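#' Configuration for the reference/mixture simulator
#'
#' Describes a synthetic flow-sorted reference experiment: K cell types
#' with replicated purified samples, cell-specific hyper- and
#' hypomethylated marker probes (planted DMRs) among uninformative
#' background probes, beta-distributed measurement noise, and a seed.
#'
#' @param nProbes Total probes (default 5000).
#' @param cellTypes Cell-type labels (default the six canonical leukocyte
#'   subtypes).
#' @param nDmrPerType Planted DMRs per cell type per direction (default
#'   100; deep enough for the default candidate pool of L/2 = 75 per
#'   direction).
#' @param replicates Reference replicates per cell type: a single count or
#'   a named vector, e.g. \code{c(CD4T = 7)} on top of a default of 6,
#'   mirroring a typical sorted-reference design. Default 6; minimum 2.
#' @param delta Methylation difference on the beta scale between the focal
#'   cell type and the others at a planted DMR (default 0.5).
#' @param phi Precision of the beta-distributed measurement noise;
#'   replicate betas are drawn \eqn{Beta(\mu\phi, (1-\mu)\phi)}.
#'   \code{Inf} gives noiseless data. Default 200.
#' @param seed Integer seed or \code{NULL}.
#' @return Validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(nProbes = 5000, cellTypes = canonicalCellTypes(),
                      nDmrPerType = 100, replicates = 6, delta = 0.5,
                      phi = 200, seed = NULL) {
    K <- length(cellTypes)
    stopifnot(K >= 2, !anyDuplicated(cellTypes), nDmrPerType >= 1,
              delta > 0, delta < 1, phi > 0)
    if (2 * K * nDmrPerType > nProbes) {
        stop("nProbes must be >= 2 * K * nDmrPerType (planted DMRs must ",
             "fit among the probes)")
    }
    reps <- stats::setNames(rep(if (is.null(names(replicates)))
        replicates[1] else 6L, K), cellTypes)
    if (!is.null(names(replicates))) {
        bad <- setdiff(names(replicates), cellTypes)
        if (length(bad)) stop("unknown cell type(s): ",
                              paste(bad, collapse = ", "))
        reps[names(replicates)] <- replicates
    }
    if (any(reps < 2)) stop("every cell type needs >= 2 replicates")
    structure(list(nProbes = as.integer(nProbes), cellTypes = cellTypes,
                   nDmrPerType = as.integer(nDmrPerType),
                   replicates = stats::setNames(as.integer(reps),
                                                names(reps)),
                   delta = delta,
                   phi = phi, seed = seed),
              class = "simConfig")
}

.rbetaPrecision <- function(mu, phi) {
    if (is.infinite(phi)) return(mu)
    mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
}

#' Simulate a replicated, cell-sorted methylation reference
#'
#' Generates latent per-cell-type mean methylomes and noisy replicate
#' samples. Background probes share one latent mean across all cell types,
#' drawn from a bimodal beta mixture (mostly-unmethylated and
#' mostly-methylated modes, as in real methylomes). Each planted DMR gives
#' its focal cell type a mean offset by exactly \code{delta} (hyper: above
#' the others; hypo: below). Replicate betas are
#' \eqn{Beta(\mu\phi, (1-\mu)\phi)} draws around the latent mean, keeping
#' support in [0, 1]. Fully reproducible under the config seed.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return List with \code{reference} (a \linkS4class{ReferenceSet}) and
#'   \code{profiles} (a \linkS4class{CellTypeProfiles} holding the latent
#'   means and the planted DMR map).
#' @export
simulateReference <- function(cfg = simConfig()) {
    stopifnot(inherits(cfg, "simConfig"))
    .withSeed(cfg$seed, {
        K <- length(cfg$cellTypes)
        p <- cfg$nProbes
        probeIds <- sprintf("cg%07d", seq_len(p))
        # latent background means, shared across cell types
        lowMode <- stats::rbinom(p, 1, 0.5) == 1
        mu0 <- ifelse(lowMode, stats::rbeta(p, 2, 10),
                      stats::rbeta(p, 10, 2))
        means <- matrix(mu0, p, K,
                        dimnames = list(probeIds, cfg$cellTypes))
        # plant DMRs at random probe positions
        nDmr <- 2L * K * cfg$nDmrPerType
        at <- sample.int(p, nDmr)
        dmr <- data.frame(
            probe_id = probeIds[at],
            cell_type = rep(cfg$cellTypes, each = 2 * cfg$nDmrPerType),
            direction = rep(rep(c("hyper", "hypo"),
                                each = cfg$nDmrPerType), K),
            stringsAsFactors = FALSE)
        for (i in seq_len(nDmr)) {
            j <- at[i]
            k <- dmr$cell_type[i]
            if (dmr$direction[i] == "hyper") {
                u <- stats::runif(1, 0.02, 0.98 - cfg$delta)
                means[j, ] <- u
                means[j, k] <- u + cfg$delta
            } else {
                u <- stats::runif(1, 0.02 + cfg$delta, 0.98)
                means[j, ] <- u
                means[j, k] <- u - cfg$delta
            }
        }
        # noisy replicates
        sampleType <- rep(cfg$cellTypes, times = cfg$replicates)
        sampleIds <- unlist(lapply(cfg$cellTypes, function(k) {
            sprintf("%s_%d", k, seq_len(cfg$replicates[[k]]))
        }))
        betas <- vapply(seq_along(sampleIds), function(s) {
            .rbetaPrecision(means[, sampleType[s]], cfg$phi)
        }, numeric(p))
        dimnames(betas) <- list(probeIds, sampleIds)
        list(reference = ReferenceSet(betas,
                                      stats::setNames(sampleType,
                                                      sampleIds)),
             profiles = new("CellTypeProfiles", means = means,
                            dmrMap = dmr))
    })
}

#' Probe library of the planted markers
#'
#' Builds the fully informative \linkS4class{ProbeLibrary} containing
#' exactly the DMRs planted by \code{\link{simulateReference}}, with the
#' theoretical effect size (signed \code{delta} on the beta scale) in
#' place of an estimated t-statistic. Useful as the oracle library in
#' recovery experiments.
#'
#' @param profiles A \linkS4class{CellTypeProfiles}.
#' @param delta Effect size recorded as the score (default 1).
#' @return A \linkS4class{ProbeLibrary}.
#' @export
plantedLibrary <- function(profiles, delta = 1) {
    stopifnot(is(profiles, "CellTypeProfiles"), delta > 0)
    d <- dmrMap(profiles)
    ProbeLibrary(d$probe_id, d$cell_type,
                 ifelse(d$direction == "hyper", delta, -delta),
                 d$direction)
}

#' Draw mixing proportions from a Dirichlet design
#'
#' Emulates the two artificial-mixture reconstruction designs: method A
#' draws from a symmetric K-component Dirichlet (near-equal proportions of
#' every cell type), method B from a Dirichlet centred on a
#' blood-realistic mean profile (neutrophil-dominated, as in adult
#' peripheral blood). Every row sums to one.
#'
#' @param method \code{"A"} (symmetric) or \code{"B"} (blood-realistic).
#' @param n Number of mixture samples (default 6 per design).
#' @param alphaScale Concentration: method A uses
#'   \eqn{\alpha_i = alphaScale}; method B uses
#'   \eqn{\alpha_i = alphaScale \cdot K \cdot p_i} so both designs share
#'   total concentration \eqn{K \cdot alphaScale}. Larger values
#'   concentrate draws around the mean. Default 50.
#' @param meanProfile Named mean profile for method B (default Neu 0.55,
#'   CD4T 0.16, CD8T 0.09, Mono 0.09, NK 0.06, Bcell 0.05).
#' @param cellTypes Labels used for method A (default canonical six).
#' @param seed Integer seed or \code{NULL}.
#' @return Samples-by-cell-types proportion matrix with rows summing to 1.
#' @export
dirichletDesign <- function(method = c("A", "B"), n = 6, alphaScale = 50,
                            meanProfile = c(Neu = 0.55, CD4T = 0.16,
                                            CD8T = 0.09, Mono = 0.09,
                                            NK = 0.06, Bcell = 0.05),
                            cellTypes = canonicalCellTypes(),
                            seed = NULL) {
    method <- match.arg(method)
    stopifnot(n >= 1, alphaScale > 0)
    if (method == "A") {
        alpha <- stats::setNames(rep(alphaScale, length(cellTypes)),
                                 cellTypes)
    } else {
        meanProfile <- meanProfile / sum(meanProfile)
        alpha <- alphaScale * length(meanProfile) * meanProfile
    }
    .withSeed(seed, {
        g <- matrix(stats::rgamma(n * length(alpha),
                                  shape = rep(alpha, each = n)),
                    nrow = n)
        props <- g / rowSums(g)
        dimnames(props) <- list(sprintf("mix%s_%d", method, seq_len(n)),
                                names(alpha))
        props
    })
}

#' Simulate artificial mixtures with known composition
#'
#' In-silico analogue of pooling purified cell DNA at known fractions: the
#' latent mixture methylation at each probe is the convex combination of
#' the cell-type latent means weighted by the mixing proportions, and the
#' observed beta is a \eqn{Beta(\mu\phi, (1-\mu)\phi)} draw around it
#' (\code{phi = Inf} gives the exact combination). Mixing acts on latent
#' means, not on noisy replicates, matching the physics of pooling DNA.
#'
#' @param profiles A \linkS4class{CellTypeProfiles} from
#'   \code{\link{simulateReference}}.
#' @param truth Samples-by-cell-types proportion matrix (rows must sum to
#'   1 within 1e-6), e.g. from \code{\link{dirichletDesign}}.
#' @param phi Measurement-noise precision (default 200; \code{Inf} for
#'   noise-free).
#' @param seed Integer seed or \code{NULL}.
#' @return Probes-by-samples beta matrix.
#' @export
simulateMixtures <- function(profiles, truth, phi = 200, seed = NULL) {
    stopifnot(is(profiles, "CellTypeProfiles"))
    truth <- .asProportionMatrix(truth)
    means <- latentMeans(profiles)
    if (!setequal(colnames(truth), colnames(means))) {
        stop("truth cell types must match the profile cell types")
    }
    if (any(abs(rowSums(truth) - 1) > 1e-6)) {
        stop("every truth row must sum to 1 (within 1e-6)")
    }
    truth <- truth[, colnames(means), drop = FALSE]
    latent <- means %*% t(truth)
    .withSeed(seed, {
        obs <- matrix(.rbetaPrecision(as.numeric(latent), phi),
                      nrow(latent), ncol(latent),
                      dimnames = dimnames(latent))
        obs
    })
}
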
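#' Configuration for the IDOL search
#'
#' Bundles the tuning parameters of the iterative library optimization:
#' candidate depth L, the library sizes swept, the iteration budget, the
#' bounded multiplicative weight-update factors, and the seed.
#'
#' @param L Candidate-depth parameter: L/2 probes per direction per cell
#'   type enter the pool (default 150).
#' @param sizes Library sizes for \code{\link{idolSizeSweep}} (default
#'   \code{seq(50, 800, by = 50)}).
#' @param iterations Search iterations per size (default 500).
#' @param seed Integer seed (or \code{NULL} to use the current RNG state).
#' @param weightUp Multiplicative increase applied to the selection weight
#'   of a probe whose removal worsens performance (default 1.2, capped at
#'   1).
#' @param weightDown Multiplicative decrease for a probe whose removal
#'   improves performance (default 0.8, floored at \code{minWeight}).
#' @param minWeight Weight floor, keeps every candidate selectable
#'   (default 0.05).
#' @param plateauTolerance Sweep plateau rule: the chosen size is the
#'   smallest whose best mean RMSE is within this many percentage points
#'   of the overall minimum (default 0.1).
#' @return Validated list of class \code{"idolConfig"}.
#' @export
idolConfig <- function(L = 150, sizes = seq(50, 800, by = 50),
                       iterations = 500, seed = NULL, weightUp = 1.2,
                       weightDown = 0.8, minWeight = 0.05,
                       plateauTolerance = 0.1) {
    stopifnot(iterations >= 1, length(sizes) >= 1, all(sizes >= 1),
              weightDown > 0, weightDown <= 1, weightUp >= 1,
              minWeight > 0, minWeight <= 1, plateauTolerance >= 0)
    structure(list(L = L, sizes = as.integer(sizes),
                   iterations = as.integer(iterations), seed = seed,
                   weightUp = weightUp, weightDown = weightDown,
                   minWeight = minWeight,
                   plateauTolerance = plateauTolerance),
              class = "idolConfig")
}

# per-cell-type r2/rmse of raw CP/QP estimates against truth, given a
# signature and the mixture rows already aligned to the reference
.scorePerCell <- function(sig, mixtures, truth, method = "cpqp") {
    est <- deconvolve(mixtures[rownames(sig), , drop = FALSE], sig,
                      method = method)
    truth <- truth[rownames(est), colnames(est), drop = FALSE]
    types <- colnames(truth)
    r2 <- rmse <- numeric(length(types))
    for (i in seq_along(types)) {
        e <- est[, i]; t <- truth[, i]
        r2[i] <- if (stats::sd(t) == 0 || stats::sd(e) == 0) NA_real_
                 else stats::cor(e, t)^2
        rmse[i] <- 100 * sqrt(mean((e - t)^2))
    }
    list(cell_type = types, r2 = r2, rmse = rmse,
         mean_rmse = mean(rmse), mean_r2 = mean(r2, na.rm = TRUE))
}

.checkTraining <- function(lib, ref, mixtures, truth) {
    mixtures <- .asBetaMatrix(mixtures, "mixture matrix")
    truth <- .asProportionMatrix(truth)
    if (ncol(mixtures) < 2) {
        stop("R2 is degenerate with fewer than 2 mixture samples")
    }
    if (!setequal(colnames(mixtures), rownames(truth))) {
        stop("truth rows must match mixture samples")
    }
    types <- sort(unique(cellTypes(ref)))
    if (!setequal(colnames(truth), types)) {
        stop("truth cell types must match the reference cell types")
    }
    miss <- setdiff(probeIds(lib), rownames(mixtures))
    if (length(miss)) {
        stop("library probe(s) absent from mixtures: ",
             paste(utils::head(miss, 5), collapse = ", "))
    }
    list(mixtures = mixtures,
         truth = truth[colnames(mixtures), types, drop = FALSE])
}

#' Score a probe library on training mixtures
#'
#' Builds the signature for \code{lib}, deconvolves the training mixtures,
#' and reports per-cell-type \eqn{R^2} and RMSE (percentage points)
#' against the known proportions — the objective IDOL optimizes.
#'
#' @param lib A \linkS4class{ProbeLibrary}.
#' @param ref A \linkS4class{ReferenceSet}.
#' @param mixtures Probes-by-samples beta matrix of training mixtures
#'   (>= 2 samples).
#' @param truth Samples-by-cell-types matrix of known mixing proportions.
#' @param method Deconvolution back-end (default \code{"cpqp"}).
#' @return data.frame with columns cell_type, r2, rmse plus a
#'   \code{"mean"} row.
#' @export
scoreLibrary <- function(lib, ref, mixtures, truth, method = "cpqp") {
    tr <- .checkTraining(lib, ref, mixtures, truth)
    sig <- buildSignature(ref, lib)
    sc <- .scorePerCell(sig, tr$mixtures, tr$truth, method)
    data.frame(cell_type = c(sc$cell_type, "mean"),
               r2 = c(sc$r2, sc$mean_r2),
               rmse = c(sc$rmse, sc$mean_rmse),
               stringsAsFactors = FALSE)
}

#' Leave-one-out probe contributions
#'
#' Removes library probes one at a time, rescores the reduced library, and
#' reports \eqn{\Delta_j = } mean RMSE(full) - mean RMSE(without j). A
#' positive \eqn{\Delta_j} means removing probe j improves accuracy (the
#' probe is harmful); a negative value means the probe is helpful. These
#' contributions drive the IDOL weight updates.
#'
#' @inheritParams scoreLibrary
#' @return Named numeric vector of \eqn{\Delta} values, one per probe.
#' @export
leaveOneOut <- function(lib, ref, mixtures, truth, method = "cpqp") {
    if (length(lib) < 2) stop("leave-one-out needs a library of >= 2 probes")
    tr <- .checkTraining(lib, ref, mixtures, truth)
    sig <- buildSignature(ref, lib)
    full <- .scorePerCell(sig, tr$mixtures, tr$truth, method)$mean_rmse
    probes <- probeIds(lib)
    deltas <- vapply(seq_along(probes), function(j) {
        full - .scorePerCell(sig[-j, , drop = FALSE], tr$mixtures,
                             tr$truth, method)$mean_rmse
    }, numeric(1))
    stats::setNames(deltas, probes)
}

#' Update IDOL selection weights from leave-one-out contributions
#'
#' The bounded multiplicative rule: a probe whose removal worsens
#' performance (\eqn{\Delta < 0}, helpful) has its weight multiplied by
#' \code{weightUp} (capped at 1); a probe whose removal improves
#' performance (\eqn{\Delta > 0}, harmful) is multiplied by
#' \code{weightDown} (floored at \code{minWeight}); \eqn{\Delta = 0} and
#' unsampled probes are unchanged.
#'
#' @param weights Named numeric vector of per-candidate weights in (0, 1].
#' @param deltas Named numeric vector from \code{\link{leaveOneOut}};
#'   names must be a subset of \code{names(weights)}.
#' @param config An \code{\link{idolConfig}}.
#' @return Updated weights vector.
#' @export
updateWeights <- function(weights, deltas, config = idolConfig()) {
    if (!all(names(deltas) %in% names(weights))) {
        stop("deltas must cover only candidates present in weights")
    }
    helpful <- names(deltas)[deltas < 0]
    harmful <- names(deltas)[deltas > 0]
    weights[helpful] <- pmin(weights[helpful] * config$weightUp, 1)
    weights[harmful] <- pmax(weights[harmful] * config$weightDown,
                             config$minWeight)
    weights
}

#' IDOL: iterative search for an optimal deconvolution library
#'
#' Searches the candidate pool for a probe subset of the requested size
#' that minimizes deconvolution error on training mixtures with known
#' composition. Every candidate starts with equal selection weight; each
#' iteration samples \code{size} probes without replacement with
#' probability proportional to the weights, scores the sampled library by
#' CP/QP deconvolution of the training mixtures, computes leave-one-out
#' probe contributions, and updates the weights so that probes that help
#' become more likely to be drawn again. The best library seen (primary
#' key: mean RMSE across cell types; ties broken by higher mean
#' \eqn{R^2}, then by lexicographic probe set) is tracked across the fixed
#' iteration budget.
#'
#' @param pool Candidate \linkS4class{ProbeLibrary} from
#'   \code{\link{buildCandidatePool}}.
#' @inheritParams scoreLibrary
#' @param size Library size to select; must be < number of candidates.
#' @param config An \code{\link{idolConfig}} (iterations, seed, weight
#'   rule).
#' @return An \linkS4class{IdolState}.
#' @export
idolOptimize <- function(pool, ref, mixtures, truth, size,
                         config = idolConfig(), method = "cpqp") {
    npool <- length(pool)
    size <- as.integer(size)
    if (size >= npool) {
        stop("library size must be smaller than the candidate pool (",
             npool, ")")
    }
    if (size < 2) stop("library size must be >= 2")
    tr <- .checkTraining(pool, ref, mixtures, truth)
    poolSig <- buildSignature(ref, pool)
    probes <- probeIds(pool)
    weights <- stats::setNames(rep(1, npool), probes)
    best <- NULL
    hist <- vector("list", config$iterations)
    .withSeed(config$seed, {
        for (it in seq_len(config$iterations)) {
            idx <- sample.int(npool, size, prob = weights)
            sig <- poolSig[idx, , drop = FALSE]
            sc <- .scorePerCell(sig, tr$mixtures, tr$truth, method)
            if (!is.finite(sc$mean_rmse)) {
                stop("non-finite library score at iteration ", it)
            }
            deltas <- vapply(seq_len(size), function(j) {
                sc$mean_rmse -
                    .scorePerCell(sig[-j, , drop = FALSE], tr$mixtures,
                                  tr$truth, method)$mean_rmse
            }, numeric(1))
            names(deltas) <- probes[idx]
            weights <- updateWeights(weights, deltas, config)
            cand <- list(idx = sort(idx), mean_rmse = sc$mean_rmse,
                         mean_r2 = sc$mean_r2)
            if (.betterLibrary(cand, best, probes)) best <- cand
            hist[[it]] <- data.frame(
                iteration = it, cell_type = sc$cell_type, r2 = sc$r2,
                rmse = sc$rmse, mean_rmse = sc$mean_rmse,
                best_mean_rmse = best$mean_rmse, stringsAsFactors = FALSE)
        }
    })
    history <- do.call(rbind, hist)
    rownames(history) <- NULL
    new("IdolState", weights = weights, bestLibrary = pool[best$idx],
        bestScore = c(mean_rmse = best$mean_rmse,
                      mean_r2 = best$mean_r2),
        history = history, config = unclass(config))
}

# ordering: lower mean RMSE, then higher mean R2, then lexicographically
# smaller probe set
.betterLibrary <- function(cand, best, probes) {
    if (is.null(best)) return(TRUE)
    if (cand$mean_rmse != best$mean_rmse) {
        return(cand$mean_rmse < best$mean_rmse)
    }
    if (cand$mean_r2 != best$mean_r2) {
        return(cand$mean_r2 > best$mean_r2)
    }
    paste(sort(probes[cand$idx]), collapse = ",") <
        paste(sort(probes[best$idx]), collapse = ",")
}

#' Sweep IDOL over a range of library sizes
#'
#' Runs an independent IDOL optimization for each requested library size
#' and picks the working size by a plateau rule: the smallest size whose
#' best mean RMSE lies within \code{plateauTolerance} percentage points of
#' the overall minimum (close-to-optimal accuracy with the fewest probes).
#' When a seed is set, size i uses seed + i - 1 so runs are independent
#' but reproducible.
#'
#' @inheritParams idolOptimize
#' @return List with \code{summary} (data.frame: size, mean_rmse,
#'   mean_r2), \code{chosenSize}, and \code{states} (named list of
#'   \linkS4class{IdolState} per size).
#' @export
idolSizeSweep <- function(pool, ref, mixtures, truth,
                          config = idolConfig(), method = "cpqp") {
    sizes <- config$sizes
    if (!length(sizes)) stop("empty size list")
    if (any(sizes >= length(pool))) {
        stop("all sizes must be smaller than the candidate pool (",
             length(pool), ")")
    }
    states <- lapply(seq_along(sizes), function(i) {
        cfg <- config
        if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + i - 1L
        idolOptimize(pool, ref, mixtures, truth, sizes[i], cfg, method)
    })
    names(states) <- as.character(sizes)
    summary <- data.frame(
        size = sizes,
        mean_rmse = vapply(states, function(s) bestScore(s)[["mean_rmse"]],
                           numeric(1)),
        mean_r2 = vapply(states, function(s) bestScore(s)[["mean_r2"]],
                         numeric(1)),
        row.names = NULL)
    ok <- summary$mean_rmse <= min(summary$mean_rmse) +
        config$plateauTolerance
    chosen <- min(summary$size[ok])
    list(summary = summary, chosenSize = chosen, states = states)
}

#' Restrict a library or pool to a probe whitelist
#'
#' Filters library entries to probes present on a given platform (for
#' example the subset of candidates also present on an earlier array
#' generation) before optimization.
#'
#' @param lib A \linkS4class{ProbeLibrary}.
#' @param probes Character vector of allowed probe ids.
#' @return The filtered \linkS4class{ProbeLibrary}.
#' @export
restrictToProbes <- function(lib, probes) {
    stopifnot(is(lib, "ProbeLibrary"))
    keep <- probeIds(lib) %in% probes
    if (!any(keep)) stop("no library probe is on the whitelist")
    lib[which(keep)]
}
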
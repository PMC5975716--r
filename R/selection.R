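#' Per-probe, per-cell-type discriminating t-statistics
#'
#' For every probe and every cell type k, a two-sample t-statistic comparing
#' mean methylation in cell type k against all other cell types pooled.
#' Positive t means hypermethylated in cell type k relative to the rest.
#' These statistics drive both automatic library selection and the IDOL
#' candidate pool.
#'
#' Missing betas are excluded pairwise. A probe missing in at least half
#' the replicates of any cell type is excluded from selection entirely
#' (its whole row is \code{NA}): the group means and variances would no
#' longer be comparable across types. Probes with zero pooled variance get
#' \code{t = 0} when the group means agree and a signed infinity otherwise
#' (a perfect separator, ranked above all finite statistics).
#'
#' @param ref A \linkS4class{ReferenceSet} (>= 2 replicates per cell type).
#' @param var.equal If \code{TRUE} (default) the classical pooled-variance
#'   two-sample t is used; \code{FALSE} gives the Welch statistic.
#' @return Numeric matrix, probes x cell types.
#' @seealso \code{\link{selectAutomatic}}, \code{\link{buildCandidatePool}}
#' @export
computeTStats <- function(ref, var.equal = TRUE) {
    stopifnot(is(ref, "ReferenceSet"))
    b <- betaValues(ref)
    ct <- cellTypes(ref)
    types <- sort(unique(ct))
    tab <- table(ct)
    if (any(tab < 2) || sum(tab) - min(tab) < 2) {
        stop("insufficient replicates: each cell type and the pooled rest ",
             "need >= 2 samples")
    }
    # probes missing in >= half of any type's replicates leave selection
    excluded <- Reduce(`|`, lapply(types, function(k) {
        g <- b[, ct == k, drop = FALSE]
        rowSums(is.na(g)) >= ncol(g) / 2
    }))
    tmat <- vapply(types, function(k) {
        .twoSampleT(b[, ct == k, drop = FALSE],
                    b[, ct != k, drop = FALSE], var.equal)
    }, numeric(nrow(b)))
    tmat <- matrix(tmat, nrow = nrow(b),
                   dimnames = list(rownames(b), types))
    tmat[excluded, ] <- NA_real_
    tmat
}

.twoSampleT <- function(g1, g2, var.equal) {
    s1 <- .rowMoments(g1)
    s2 <- .rowMoments(g2)
    diff <- s1$mean - s2$mean
    se <- if (var.equal) {
        sp2 <- ((s1$n - 1) * s1$var + (s2$n - 1) * s2$var) /
               (s1$n + s2$n - 2)
        sqrt(sp2 * (1 / s1$n + 1 / s2$n))
    } else {
        sqrt(s1$var / s1$n + s2$var / s2$n)
    }
    t <- diff / se
    degenerate <- !is.na(se) & se == 0
    t[degenerate] <- sign(diff[degenerate]) * Inf
    t[degenerate & diff == 0] <- 0
    t[s1$n < 2 | s2$n < 2] <- NA_real_
    t
}

.rowMoments <- function(g) {
    n <- rowSums(!is.na(g))
    m <- rowMeans(g, na.rm = TRUE)
    v <- rowSums((g - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mean = m, var = v)
}

# top-n probes per cell type and direction, ranked on t, ties broken by
# ascending probe id; duplicate probes across cell types collapse to the
# entry with the largest |t| (then lexicographic cell type)
.selectTop <- function(tstats, n, context) {
    stopifnot(is.matrix(tstats), !is.null(rownames(tstats)))
    types <- colnames(tstats)
    rows <- list()
    for (k in types) {
        t <- tstats[, k]
        ok <- !is.na(t)
        for (dir in c("hyper", "hypo")) {
            cand <- if (dir == "hyper") ok & t > 0 else ok & t < 0
            ids <- rownames(tstats)[cand]
            tv <- t[cand]
            if (length(ids) < n) {
                stop(sprintf(
                    "%s: cell type '%s' has only %d %smethylated probes (%d needed)",
                    context, k, length(ids), dir, n))
            }
            o <- if (dir == "hyper") order(-tv, ids) else order(tv, ids)
            pick <- o[seq_len(n)]
            rows[[paste(k, dir)]] <- data.frame(
                probe_id = ids[pick], cell_type = k, direction = dir,
                t_stat = tv[pick], stringsAsFactors = FALSE)
        }
    }
    e <- do.call(rbind, rows)
    rownames(e) <- NULL
    # deduplicate cross-cell-type collisions: keep the largest |t| entry,
    # ties by lexicographic cell type
    if (anyDuplicated(e$probe_id)) {
        e <- e[order(e$probe_id, -abs(e$t_stat), e$cell_type), ]
        e <- e[!duplicated(e$probe_id), ]
    }
    e <- e[order(e$cell_type, e$direction, -abs(e$t_stat), e$probe_id), ]
    rownames(e) <- NULL
    new("ProbeLibrary", entries = e)
}

#' Automatic probe-library selection
#'
#' The classical rank-based selection: for each cell type, the
#' \code{nPerDirection} probes with the largest t-statistics
#' (hypermethylated) and the \code{nPerDirection} with the smallest
#' (hypomethylated), pooled over all K cell types and deduplicated. With
#' the default of 50 per direction and six cell types this yields the
#' familiar 600-probe deconvolution library (fewer if the per-type top
#' lists overlap). Ties at the rank boundary are broken by ascending probe
#' id so the selection is deterministic.
#'
#' @param tstats Matrix from \code{\link{computeTStats}}.
#' @param nPerDirection Probes per cell type per direction (default 50).
#' @return A \linkS4class{ProbeLibrary}.
#' @export
selectAutomatic <- function(tstats, nPerDirection = 50) {
    stopifnot(nPerDirection >= 1)
    .selectTop(tstats, as.integer(nPerDirection), "automatic selection")
}

#' Candidate pool for IDOL optimization
#'
#' Pools the L/2 probes with the largest and the L/2 with the smallest
#' t-statistic for each cell type, deduplicated: at most L*K unique
#' candidates. This pool is the search space over which
#' \code{\link{idolOptimize}} looks for an optimal deconvolution library.
#' The default depth L = 150 gives up to 900 candidates for K = 6.
#'
#' @param tstats Matrix from \code{\link{computeTStats}}.
#' @param L Candidate depth per cell type; must be even (L/2 per
#'   direction). Default 150.
#' @return A \linkS4class{ProbeLibrary} of <= L*K candidates.
#' @export
buildCandidatePool <- function(tstats, L = 150) {
    L <- as.integer(L)
    if (L < 2 || L %% 2 != 0) {
        stop("L must be an even count >= 2")
    }
    .selectTop(tstats, L %/% 2L, "candidate pool")
}
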
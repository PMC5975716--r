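#' Per-cell-type accuracy of deconvolution estimates
#'
#' Compares estimated to true cell fractions sample-wise. For each cell
#' type: \eqn{R^2}, the squared Pearson correlation of estimate versus
#' truth across samples (set \code{r2 = "one_minus_ss"} for the
#' \eqn{1 - SS_{res}/SS_{tot}} definition), and the RMSE in percentage
#' points. Also returns the full error table (signed and absolute errors,
#' percentage points).
#'
#' @param est,truth Samples-by-cell-types proportion matrices with matching
#'   dimnames (order-insensitive).
#' @param r2 \code{"pearson"} (default, squared correlation) or
#'   \code{"one_minus_ss"}.
#' @return List with \code{performance} (data.frame: cell_type, r2, rmse,
#'   plus a \code{"mean"} row averaging across cell types) and
#'   \code{errors} (data.frame: sample_id, cell_type, signed_error,
#'   abs_error, percentage points).
#' @export
performanceStats <- function(est, truth, r2 = c("pearson", "one_minus_ss")) {
    r2 <- match.arg(r2)
    al <- .alignToSamples(est, truth)
    est <- al$est; truth <- al$truth
    if (nrow(truth) < 2) {
        stop("R2 is undefined for fewer than 2 samples")
    }
    types <- colnames(truth)
    perf <- do.call(rbind, lapply(types, function(k) {
        e <- est[, k]; t <- truth[, k]
        r2v <- if (r2 == "pearson") {
            if (stats::sd(t) == 0 || stats::sd(e) == 0) NA_real_
            else stats::cor(e, t)^2
        } else {
            1 - sum((e - t)^2) / sum((t - mean(t))^2)
        }
        data.frame(cell_type = k, r2 = r2v,
                   rmse = 100 * sqrt(mean((e - t)^2)),
                   stringsAsFactors = FALSE)
    }))
    perf <- rbind(perf, data.frame(cell_type = "mean",
                                   r2 = mean(perf$r2, na.rm = TRUE),
                                   rmse = mean(perf$rmse)))
    rownames(perf) <- NULL
    diff <- 100 * (est - truth)
    errors <- data.frame(
        sample_id = rep(rownames(truth), times = length(types)),
        cell_type = rep(types, each = nrow(truth)),
        signed_error = as.numeric(diff),
        abs_error = abs(as.numeric(diff)),
        stringsAsFactors = FALSE)
    list(performance = perf, errors = errors)
}

#' Bland-Altman agreement between estimates and truth
#'
#' Per cell type: the mean paired difference (estimate minus truth, in
#' percentage points) and its 95\% limits of agreement,
#' mean \eqn{\pm 1.96 \cdot SD} of the differences.
#'
#' @inheritParams performanceStats
#' @return data.frame with columns cell_type, mean_diff, lower, upper.
#' @export
blandAltman <- function(est, truth) {
    al <- .alignToSamples(est, truth)
    if (nrow(al$truth) < 2) {
        stop("limits of agreement are undefined for a single sample")
    }
    diff <- 100 * (al$est - al$truth)
    out <- do.call(rbind, lapply(colnames(diff), function(k) {
        d <- diff[, k]
        m <- mean(d); s <- stats::sd(d)
        data.frame(cell_type = k, mean_diff = m,
                   lower = m - 1.96 * s, upper = m + 1.96 * s,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Paired t-test of estimates against truth
#'
#' Tests whether deconvolution estimates are systematically biased with
#' respect to the known fractions: a paired t-test on (estimate - truth),
#' either per cell type or pooling all sample-by-cell-type pairs
#' (\code{scope = "global"}). Zero-variance differences with a non-zero
#' mean are an exact bias: reported with a signed infinite t, p = 0 and
#' \code{exact_bias = TRUE} rather than an error.
#'
#' @inheritParams performanceStats
#' @param scope \code{"per_cell"} (default) or \code{"global"}.
#' @return data.frame with columns cell_type (or \code{"global"}),
#'   mean_diff (percentage points), t, df, p, exact_bias.
#' @export
pairedT <- function(est, truth, scope = c("per_cell", "global")) {
    scope <- match.arg(scope)
    al <- .alignToSamples(est, truth)
    diff <- 100 * (al$est - al$truth)
    groups <- if (scope == "global") {
        list(global = as.numeric(diff))
    } else {
        stats::setNames(lapply(colnames(diff), function(k) diff[, k]),
                        colnames(diff))
    }
    out <- do.call(rbind, lapply(names(groups), function(k) {
        d <- groups[[k]]
        if (length(d) < 2) stop("paired t-test needs >= 2 pairs")
        # differences constant up to floating-point noise: exact bias
        if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
            m <- mean(d)
            data.frame(cell_type = k, mean_diff = m,
                       t = if (m == 0) 0 else sign(m) * Inf,
                       df = length(d) - 1,
                       p = if (m == 0) 1 else 0,
                       exact_bias = m != 0, stringsAsFactors = FALSE)
        } else {
            tt <- stats::t.test(d)
            data.frame(cell_type = k, mean_diff = mean(d),
                       t = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value, exact_bias = FALSE,
                       stringsAsFactors = FALSE)
        }
    }))
    rownames(out) <- NULL
    out
}

#' Bartlett test of error-variance homogeneity across methods
#'
#' Compares the spread of deconvolution errors between methods (or any
#' grouping): Bartlett's test of homogeneity of variances with its
#' chi-squared p-value. Used to ask whether one library/back-end yields
#' systematically tighter estimates than another.
#'
#' @param errors Named list of numeric error vectors, one per method, each
#'   of length >= 2.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
bartlettAcrossMethods <- function(errors) {
    if (!is.list(errors) || length(errors) < 2) {
        stop("need >= 2 groups of errors")
    }
    if (any(vapply(errors, length, 1L) < 2)) {
        stop("every group needs >= 2 values")
    }
    if (any(vapply(errors, stats::var, 1) == 0)) {
        stop("Bartlett statistic is undefined for a zero-variance group")
    }
    bt <- stats::bartlett.test(errors)
    list(statistic = unname(bt$statistic), df = unname(bt$parameter),
         p = bt$p.value)
}

#' Immune cell ratios from estimated proportions
#'
#' Clinically interpreted lineage ratios per sample: the neutrophil to
#' lymphocyte ratio NLR = Neu / (Bcell + CD4T + CD8T + NK), CD4T/CD8T,
#' (CD8T + Mono)/NK, and CD8T/Bcell. A zero denominator yields \code{NA}
#' (flagged missing), never an infinity.
#'
#' @param props Samples-by-cell-types proportion matrix containing the six
#'   canonical types (\code{\link{canonicalCellTypes}}).
#' @return data.frame with columns sample_id, nlr, cd4t_cd8t,
#'   cd8t_mono_nk, cd8t_bcell.
#' @export
cellRatios <- function(props) {
    props <- .asProportionMatrix(props)
    need <- canonicalCellTypes()
    miss <- setdiff(need, colnames(props))
    if (length(miss)) {
        stop("missing canonical cell type(s): ",
             paste(miss, collapse = ", "))
    }
    p <- props[, need, drop = FALSE]
    safeDiv <- function(num, den) ifelse(den == 0, NA_real_, num / den)
    lymph <- p[, "Bcell"] + p[, "CD4T"] + p[, "CD8T"] + p[, "NK"]
    data.frame(
        sample_id = rownames(p),
        nlr = safeDiv(p[, "Neu"], lymph),
        cd4t_cd8t = safeDiv(p[, "CD4T"], p[, "CD8T"]),
        cd8t_mono_nk = safeDiv(p[, "CD8T"] + p[, "Mono"], p[, "NK"]),
        cd8t_bcell = safeDiv(p[, "CD8T"], p[, "Bcell"]),
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Chi-squared comparison of library genomic-context composition
#'
#' Omnibus Pearson chi-squared test (no continuity correction) on a
#' libraries-by-categories contingency table of probe counts, e.g. CpG
#' island / shore / shelf / open sea counts for competing probe libraries.
#'
#' @param counts Numeric matrix or table: rows = libraries, columns =
#'   annotation categories, >= 2 of each; non-negative counts with no
#'   all-zero row or column.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
libraryContextChisq <- function(counts) {
    counts <- as.matrix(counts)
    if (nrow(counts) < 2 || ncol(counts) < 2) {
        stop("need >= 2 libraries and >= 2 categories")
    }
    if (any(counts < 0) || anyNA(counts)) {
        stop("counts must be non-negative and complete")
    }
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
        stop("degenerate table: all-zero row or column")
    }
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Count library probes per annotation category
#'
#' Convenience tabulation used as input to
#' \code{\link{libraryContextChisq}}: cross-tabulates the probes of one or
#' more libraries against a probe-annotation table.
#'
#' @param libs Named list of \linkS4class{ProbeLibrary} objects.
#' @param annotation data.frame with a \code{probe_id} column and one
#'   annotation column named by \code{category}.
#' @param category Column of \code{annotation} to tabulate (default
#'   \code{"island_context"}).
#' @return Counts matrix, libraries x categories.
#' @export
libraryContextCounts <- function(libs, annotation,
                                 category = "island_context") {
    stopifnot(is.list(libs), !is.null(names(libs)))
    if (!all(c("probe_id", category) %in% colnames(annotation))) {
        stop("annotation needs columns 'probe_id' and '", category, "'")
    }
    ann <- stats::setNames(as.character(annotation[[category]]),
                           annotation$probe_id)
    cats <- sort(unique(unname(ann)))
    out <- t(vapply(libs, function(l) {
        a <- ann[probeIds(l)]
        if (anyNA(a)) stop("unannotated probe(s) in library")
        as.numeric(table(factor(a, levels = cats)))
    }, numeric(length(cats))))
    colnames(out) <- cats
    out
}
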
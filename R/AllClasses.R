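#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Canonical leukocyte cell-type labels
#'
#' The six adult peripheral-blood leukocyte subtypes the package works with
#' by default: neutrophils (Neu), monocytes (Mono), B lymphocytes (Bcell),
#' T helper lymphocytes (CD4T), T cytotoxic lymphocytes (CD8T) and natural
#' killer lymphocytes (NK).
#'
#' @return Character vector of the six labels.
#' @examples
#' canonicalCellTypes()
#' @export
canonicalCellTypes <- function() {
    c("Neu", "Mono", "Bcell", "CD4T", "CD8T", "NK")
}

# ---------------------------------------------------------------------------
# ReferenceSet
# ---------------------------------------------------------------------------

#' ReferenceSet: cell-type-labelled reference methylomes
#'
#' A \linkS4class{SummarizedExperiment} holding a probes-by-samples matrix of
#' methylation beta values (assay \code{"beta"}) for purified, replicated
#' reference samples, with a \code{cell_type} column in \code{colData}
#' assigning each sample to one of K cell types. Validity requires all
#' non-missing betas in [0, 1], unique probe and sample identifiers, K >= 2
#' cell types and at least two replicates per type (needed for a variance
#' estimate in probe selection).
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}.
#' @aliases ReferenceSet-class
#' @exportClass ReferenceSet
setClass("ReferenceSet", contains = "SummarizedExperiment")

.validBetaValues <- function(x, what = "beta matrix") {
    v <- x[!is.na(x)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
        return(sprintf("%s contains values outside [0, 1]", what))
    }
    NULL
}

.validReferenceSet <- function(object) {
    msg <- NULL
    if (!"beta" %in% SummarizedExperiment::assayNames(object)) {
        return("assay 'beta' is required")
    }
    b <- SummarizedExperiment::assay(object, "beta")
    msg <- c(msg, .validBetaValues(b))
    if (anyDuplicated(rownames(b))) {
        msg <- c(msg, "duplicated probe identifiers")
    }
    if (anyDuplicated(colnames(b))) {
        msg <- c(msg, "duplicated sample identifiers")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"cell_type" %in% colnames(cd)) {
        return(c(msg, "colData must contain a 'cell_type' column"))
    }
    ct <- as.character(cd$cell_type)
    if (anyNA(ct)) msg <- c(msg, "every sample needs a cell-type label")
    tab <- table(ct)
    if (length(tab) < 2) {
        msg <- c(msg, "at least two distinct cell types are required")
    }
    if (any(tab < 2)) {
        msg <- c(msg, sprintf(
            "every cell type needs >= 2 replicates; offending: %s",
            paste(names(tab)[tab < 2], collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("ReferenceSet", .validReferenceSet)

#' Construct a ReferenceSet
#'
#' @param betas Numeric matrix of beta values, probes in rows, samples in
#'   columns; dimnames required. Missing values allowed as \code{NA}.
#' @param cellTypes Character vector of cell-type labels, one per sample,
#'   either named by sample id or in column order of \code{betas}.
#' @return A \linkS4class{ReferenceSet}.
#' @examples
#' b <- matrix(runif(40), 10, 4,
#'             dimnames = list(paste0("cg", 1:10), paste0("s", 1:4)))
#' ReferenceSet(b, c("CD4T", "CD4T", "NK", "NK"))
#' @export
ReferenceSet <- function(betas, cellTypes) {
    betas <- .asBetaMatrix(betas)
    if (!is.null(names(cellTypes))) {
        miss <- setdiff(colnames(betas), names(cellTypes))
        if (length(miss)) {
            stop("no cell-type label for sample(s): ",
                 paste(miss, collapse = ", "))
        }
        cellTypes <- cellTypes[colnames(betas)]
    } else if (length(cellTypes) != ncol(betas)) {
        stop("cellTypes must have one label per sample")
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(beta = betas),
        colData = S4Vectors::DataFrame(
            cell_type = as.character(cellTypes),
            row.names = colnames(betas)))
    new("ReferenceSet", se)
}

# ---------------------------------------------------------------------------
# ProbeLibrary
# ---------------------------------------------------------------------------

#' ProbeLibrary: a set of cell-type-discriminating probes
#'
#' An ordered collection of (probe, cell type, direction, t-statistic)
#' records — an L-DMR library. Direction is \code{"hyper"} for probes
#' hypermethylated in their cell type relative to all other types pooled
#' (positive t) and \code{"hypo"} for the reverse (negative t). A probe
#' appears at most once.
#'
#' @slot entries \code{data.frame} with columns \code{probe_id},
#'   \code{cell_type}, \code{direction}, \code{t_stat}.
#' @aliases ProbeLibrary-class
#' @exportClass ProbeLibrary
setClass("ProbeLibrary", representation(entries = "data.frame"))

.validProbeLibrary <- function(object) {
    e <- object@entries
    need <- c("probe_id", "cell_type", "direction", "t_stat")
    if (!all(need %in% colnames(e))) {
        return(sprintf("entries must have columns %s",
                       paste(need, collapse = ", ")))
    }
    msg <- NULL
    if (anyDuplicated(e$probe_id)) {
        msg <- c(msg, "a probe may appear only once in a library")
    }
    if (!all(e$direction %in% c("hyper", "hypo"))) {
        msg <- c(msg, "direction must be 'hyper' or 'hypo'")
    }
    fin <- is.finite(e$t_stat)
    bad <- (e$direction == "hyper" & e$t_stat <= 0 & fin) |
           (e$direction == "hypo" & e$t_stat >= 0 & fin)
    bad <- bad | (e$direction == "hyper" & e$t_stat < 0) |
                 (e$direction == "hypo" & e$t_stat > 0)
    if (any(bad, na.rm = TRUE)) {
        msg <- c(msg, "direction must match the sign of t_stat")
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("ProbeLibrary", .validProbeLibrary)

#' Construct a ProbeLibrary
#'
#' @param probe_id Character vector of probe identifiers (unique).
#' @param cell_type Character vector: the cell type each probe discriminates.
#' @param t_stat Numeric t-statistics (positive = hypermethylated in
#'   \code{cell_type} versus the pooled rest).
#' @param direction Optional \code{"hyper"}/\code{"hypo"}; derived from the
#'   sign of \code{t_stat} when omitted.
#' @return A \linkS4class{ProbeLibrary}.
#' @examples
#' ProbeLibrary(c("cg01", "cg02"), c("NK", "NK"), t_stat = c(12.3, -8.1))
#' @export
ProbeLibrary <- function(probe_id, cell_type, t_stat,
                         direction = ifelse(t_stat > 0, "hyper", "hypo")) {
    e <- data.frame(probe_id = as.character(probe_id),
                    cell_type = as.character(cell_type),
                    direction = as.character(direction),
                    t_stat = as.numeric(t_stat),
                    stringsAsFactors = FALSE)
    rownames(e) <- NULL
    new("ProbeLibrary", entries = e)
}

# ---------------------------------------------------------------------------
# CellTypeProfiles (simulation ground truth)
# ---------------------------------------------------------------------------

#' CellTypeProfiles: latent mean methylomes with a planted DMR map
#'
#' Ground truth produced by \code{\link{simulateReference}}: the latent
#' per-probe, per-cell-type mean beta values and a map recording which
#' probes were planted as cell-specific DMRs (and in which direction).
#'
#' @slot means numeric matrix, probes x cell types, latent mean betas.
#' @slot dmrMap \code{data.frame} with columns \code{probe_id},
#'   \code{cell_type}, \code{direction} for the planted markers.
#' @aliases CellTypeProfiles-class
#' @exportClass CellTypeProfiles
setClass("CellTypeProfiles",
         representation(means = "matrix", dmrMap = "data.frame"))

setValidity("CellTypeProfiles", function(object) {
    msg <- .validBetaValues(object@means, "latent means")
    if (!all(c("probe_id", "cell_type", "direction") %in%
             colnames(object@dmrMap))) {
        msg <- c(msg, "dmrMap needs probe_id, cell_type, direction columns")
    }
    if (is.null(msg)) TRUE else msg
})

# ---------------------------------------------------------------------------
# IdolState
# ---------------------------------------------------------------------------

#' IdolState: result of an IDOL optimization run
#'
#' Holds the per-candidate selection weights after the final iteration, the
#' best library found, its score, and the per-iteration performance history.
#'
#' @slot weights named numeric, per-candidate selection weight in
#'   [minWeight, 1].
#' @slot bestLibrary \linkS4class{ProbeLibrary}, best-so-far library.
#' @slot bestScore named numeric: \code{mean_rmse} (percentage points) and
#'   \code{mean_r2} of the best library on the training mixtures.
#' @slot history \code{data.frame} with columns \code{iteration},
#'   \code{cell_type}, \code{r2}, \code{rmse} for each sampled library, plus
#'   the running best mean RMSE (\code{best_mean_rmse}).
#' @slot config list, the \code{\link{idolConfig}} used.
#' @aliases IdolState-class
#' @exportClass IdolState
setClass("IdolState",
         representation(weights = "numeric", bestLibrary = "ProbeLibrary",
                        bestScore = "numeric", history = "data.frame",
                        config = "list"))

setValidity("IdolState", function(object) {
    w <- object@weights
    if (length(w) && (any(w <= 0) || any(w > 1))) {
        return("weights must lie in (0, 1]")
    }
    TRUE
})
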
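#' Read a beta-value matrix from CSV/TSV
#'
#' Reads a probes-by-samples matrix of methylation beta values. The first
#' column holds probe identifiers and the header row holds sample
#' identifiers. Values must lie in [0, 1]; out-of-range values are rejected
#' (never clamped) with an error naming the offending probe and sample.
#' Empty cells and \code{NA} are parsed as missing.
#'
#' @param path Path to the file.
#' @param dialect \code{"csv"} or \code{"tsv"}; guessed from the file
#'   extension by default.
#' @return Numeric matrix, probes in rows, samples in columns.
#' @seealso \code{\link{writeBetaMatrix}}, \code{\link{readSampleSheet}}
#' @export
readBetaMatrix <- function(path, dialect = c("auto", "csv", "tsv")) {
    dialect <- match.arg(dialect)
    sep <- .dialectSep(path, dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            row.names = NULL, check.names = FALSE,
                            na.strings = c("NA", ""),
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed matrix file: ", path)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    .asBetaMatrix(m)
}

.dialectSep <- function(path, dialect) {
    if (dialect == "auto") {
        dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
            "tsv" else "csv"
    }
    c(csv = ",", tsv = "\t")[[dialect]]
}

#' Write a beta-value matrix to CSV/TSV
#'
#' @param betas Numeric probes-by-samples matrix with dimnames.
#' @param path Output path.
#' @param dialect \code{"csv"} or \code{"tsv"} (default from extension).
#' @return \code{path}, invisibly.
#' @export
writeBetaMatrix <- function(betas, path, dialect = c("auto", "csv", "tsv")) {
    dialect <- match.arg(dialect)
    betas <- .asBetaMatrix(betas)
    sep <- .dialectSep(path, dialect)
    df <- data.frame(probe_id = rownames(betas), betas,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet assigns a cell-type label to each reference sample; target
#' (mixture) samples carry the label \code{"MIX"}.
#'
#' @param path CSV with columns \code{sample_id} and \code{cell_type}.
#' @return Named character vector of labels, names are sample ids.
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "cell_type") %in% colnames(df))) {
        stop("sample sheet needs columns sample_id, cell_type")
    }
    if (anyDuplicated(df$sample_id)) {
        stop("duplicate sample id(s) in sample sheet")
    }
    stats::setNames(as.character(df$cell_type), df$sample_id)
}

#' Write a sample sheet
#'
#' @param cellTypes Named character vector (names = sample ids).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSampleSheet <- function(cellTypes, path) {
    utils::write.csv(data.frame(sample_id = names(cellTypes),
                                cell_type = as.character(cellTypes)),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read/write a probe library
#'
#' Libraries are stored as CSV with columns \code{probe_id},
#' \code{cell_type}, \code{direction}, \code{t_stat} and round-trip
#' losslessly.
#'
#' @param path File path.
#' @return \code{readProbeLibrary}: a \linkS4class{ProbeLibrary}.
#' @export
readProbeLibrary <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("probe_id", "cell_type", "direction", "t_stat")
    if (!all(need %in% colnames(df))) {
        stop("library file needs columns ", paste(need, collapse = ", "))
    }
    ProbeLibrary(df$probe_id, df$cell_type, df$t_stat, df$direction)
}

#' @rdname readProbeLibrary
#' @param lib A \linkS4class{ProbeLibrary}.
#' @export
writeProbeLibrary <- function(lib, path) {
    stopifnot(is(lib, "ProbeLibrary"))
    utils::write.csv(libraryEntries(lib), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' Read/write a proportion matrix
#'
#' Proportion tables (true or estimated cell fractions) are CSV with a
#' \code{sample_id} column followed by one column per cell type.
#'
#' @param path File path.
#' @return \code{readProportions}: samples-by-cell-types numeric matrix.
#' @export
readProportions <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    .asProportionMatrix(m)
}

#' @rdname readProportions
#' @param props Samples-by-cell-types numeric matrix with dimnames.
#' @export
writeProportions <- function(props, path) {
    props <- .asProportionMatrix(props)
    df <- data.frame(sample_id = rownames(props), props,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Load a ReferenceSet from a beta matrix and sample sheet
#'
#' Samples labelled \code{"MIX"} in the sheet are excluded from the
#' reference and returned separately as a target matrix.
#'
#' @param betaPath Path to the beta matrix (CSV/TSV).
#' @param sheetPath Path to the sample sheet CSV.
#' @return List with elements \code{reference} (\linkS4class{ReferenceSet})
#'   and \code{mixtures} (beta matrix of the MIX samples; NULL if none).
#' @export
readReferenceSet <- function(betaPath, sheetPath) {
    betas <- readBetaMatrix(betaPath)
    ct <- readSampleSheet(sheetPath)
    miss <- setdiff(colnames(betas), names(ct))
    if (length(miss)) {
        stop("sample sheet is missing sample(s): ",
             paste(miss, collapse = ", "))
    }
    ct <- ct[colnames(betas)]
    isMix <- ct == "MIX"
    mix <- if (any(isMix)) betas[, isMix, drop = FALSE] else NULL
    list(reference = ReferenceSet(betas[, !isMix, drop = FALSE],
                                  ct[!isMix]),
         mixtures = mix)
}
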
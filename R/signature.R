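#' Build a signature matrix from a reference set and probe library
#'
#' The signature (basis) matrix used for deconvolution: for each library
#' probe and each of the K cell types, the arithmetic mean beta over that
#' cell type's reference replicates, with missing replicate values excluded
#' pairwise. Row order follows the library.
#'
#' @param ref A \linkS4class{ReferenceSet}.
#' @param lib A \linkS4class{ProbeLibrary}; every probe must be present in
#'   \code{ref}.
#' @return Numeric matrix, library probes x K cell types (columns in sorted
#'   cell-type order), values in [0, 1].
#' @examples
#' ref <- ReferenceSet(
#'   matrix(runif(40), 10, 4,
#'          dimnames = list(paste0("cg", 1:10), paste0("s", 1:4))),
#'   c("NK", "NK", "CD4T", "CD4T"))
#' lib <- ProbeLibrary(c("cg1", "cg2"), c("NK", "CD4T"), c(5, -5))
#' buildSignature(ref, lib)
#' @export
buildSignature <- function(ref, lib) {
    stopifnot(is(ref, "ReferenceSet"), is(lib, "ProbeLibrary"))
    probes <- probeIds(lib)
    missing <- setdiff(probes, rownames(ref))
    if (length(missing)) {
        stop("library probe(s) absent from reference: ",
             paste(missing, collapse = ", "))
    }
    b <- betaValues(ref)[probes, , drop = FALSE]
    ct <- cellTypes(ref)
    types <- sort(unique(ct))
    sig <- vapply(types, function(k) {
        rowMeans(b[, ct == k, drop = FALSE], na.rm = TRUE)
    }, numeric(length(probes)))
    sig <- matrix(sig, nrow = length(probes),
                  dimnames = list(probes, types))
    if (anyNA(sig) || any(is.nan(sig))) {
        bad <- rownames(sig)[apply(sig, 1, function(r) any(!is.finite(r)))]
        stop("no non-missing reference values for probe(s): ",
             paste(bad, collapse = ", "))
    }
    sig
}
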
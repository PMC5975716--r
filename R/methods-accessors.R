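#' Cell-type labels of reference samples
#'
#' @param x A \linkS4class{ReferenceSet}, a \linkS4class{ProbeLibrary} (the
#'   distinct cell types its probes discriminate) or a
#'   \linkS4class{CellTypeProfiles}.
#' @return For a \code{ReferenceSet}, a named character vector (one label
#'   per sample); otherwise the distinct cell-type labels.
#' @name cellTypes
#' @aliases cellTypes,ReferenceSet-method cellTypes,ProbeLibrary-method
#'   cellTypes,CellTypeProfiles-method
NULL

#' @export
setMethod("cellTypes", "ReferenceSet", function(x) {
    ct <- as.character(SummarizedExperiment::colData(x)$cell_type)
    names(ct) <- colnames(x)
    ct
})

#' @export
setMethod("cellTypes", "ProbeLibrary", function(x) {
    sort(unique(x@entries$cell_type))
})

#' @export
setMethod("cellTypes", "CellTypeProfiles", function(x) colnames(x@means))

#' Beta-value matrix of a ReferenceSet
#'
#' @param x A \linkS4class{ReferenceSet}.
#' @return Numeric matrix, probes x samples.
#' @name betaValues
#' @aliases betaValues,ReferenceSet-method
NULL

#' @export
setMethod("betaValues", "ReferenceSet", function(x) {
    SummarizedExperiment::assay(x, "beta")
})

#' Probe identifiers
#'
#' @param x A \linkS4class{ProbeLibrary}, \linkS4class{ReferenceSet} or
#'   \linkS4class{CellTypeProfiles}.
#' @return Character vector of probe ids (library order for libraries).
#' @name probeIds
#' @aliases probeIds,ProbeLibrary-method probeIds,ReferenceSet-method
#'   probeIds,CellTypeProfiles-method
NULL

#' @export
setMethod("probeIds", "ProbeLibrary", function(x) x@entries$probe_id)
#' @export
setMethod("probeIds", "ReferenceSet", function(x) rownames(x))
#' @export
setMethod("probeIds", "CellTypeProfiles", function(x) rownames(x@means))

#' Entries of a ProbeLibrary
#'
#' @param x A \linkS4class{ProbeLibrary}.
#' @return \code{data.frame} with columns \code{probe_id}, \code{cell_type},
#'   \code{direction}, \code{t_stat}.
#' @name libraryEntries
#' @aliases libraryEntries,ProbeLibrary-method
NULL

#' @export
setMethod("libraryEntries", "ProbeLibrary", function(x) x@entries)

#' @describeIn ProbeLibrary number of probes in the library
#' @param x A \linkS4class{ProbeLibrary}.
#' @export
setMethod("length", "ProbeLibrary", function(x) nrow(x@entries))

#' @describeIn ProbeLibrary subset by position, probe id or logical mask
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ProbeLibrary", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@entries$probe_id)
    new("ProbeLibrary", entries = x@entries[i, , drop = FALSE])
})

#' Accessors for IdolState
#'
#' @param x An \linkS4class{IdolState}.
#' @return \code{bestLibrary}: the best \linkS4class{ProbeLibrary} found;
#'   \code{bestScore}: named numeric \code{c(mean_rmse, mean_r2)};
#'   \code{idolHistory}: per-iteration, per-cell-type performance
#'   \code{data.frame}; \code{idolWeights}: final per-candidate selection
#'   weights.
#' @name bestLibrary
#' @aliases bestLibrary,IdolState-method bestScore bestScore,IdolState-method
#'   idolHistory idolHistory,IdolState-method idolWeights
#'   idolWeights,IdolState-method
NULL

#' @export
setMethod("bestLibrary", "IdolState", function(x) x@bestLibrary)
#' @export
setMethod("bestScore", "IdolState", function(x) x@bestScore)
#' @export
setMethod("idolHistory", "IdolState", function(x) x@history)
#' @export
setMethod("idolWeights", "IdolState", function(x) x@weights)

#' Accessors for CellTypeProfiles
#'
#' @param x A \linkS4class{CellTypeProfiles}.
#' @return \code{latentMeans}: probes x cell-types matrix of latent mean
#'   betas; \code{dmrMap}: \code{data.frame} of planted markers.
#' @name latentMeans
#' @aliases latentMeans,CellTypeProfiles-method dmrMap
#'   dmrMap,CellTypeProfiles-method
NULL

#' @export
setMethod("latentMeans", "CellTypeProfiles", function(x) x@means)
#' @export
setMethod("dmrMap", "CellTypeProfiles", function(x) x@dmrMap)

#' @export
setMethod("show", "ReferenceSet", function(object) {
    ct <- cellTypes(object)
    tab <- table(ct)
    cat("ReferenceSet with", nrow(object), "probes,", ncol(object),
        "samples,", length(tab), "cell types\n")
    cat(paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
})

#' @export
setMethod("show", "ProbeLibrary", function(object) {
    e <- object@entries
    cat("ProbeLibrary with", nrow(e), "probes\n")
    if (nrow(e)) {
        tab <- table(e$cell_type, e$direction)
        print(tab)
    }
})

#' @export
setMethod("show", "IdolState", function(object) {
    cat("IdolState:", length(object@weights), "candidates,",
        length(bestLibrary(object)), "probes in best library\n")
    s <- object@bestScore
    cat(sprintf("best mean RMSE %.4f pp, mean R2 %.4f (%d iterations)\n",
                s[["mean_rmse"]], s[["mean_r2"]],
                max(object@history$iteration, 0)))
})

#' @export
setMethod("show", "CellTypeProfiles", function(object) {
    cat("CellTypeProfiles:", nrow(object@means), "probes x",
        ncol(object@means), "cell types;", nrow(object@dmrMap),
        "planted DMRs\n")
})
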
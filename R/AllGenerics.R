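#' @rdname cellTypes
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname betaValues
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname probeIds
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname libraryEntries
#' @export
setGeneric("libraryEntries", function(x) standardGeneric("libraryEntries"))

#' @rdname bestLibrary
#' @export
setGeneric("bestLibrary", function(x) standardGeneric("bestLibrary"))

#' @rdname bestScore
#' @export
setGeneric("bestScore", function(x) standardGeneric("bestScore"))

#' @rdname idolHistory
#' @export
setGeneric("idolHistory", function(x) standardGeneric("idolHistory"))

#' @rdname idolWeights
#' @export
setGeneric("idolWeights", function(x) standardGeneric("idolWeights"))

#' @rdname latentMeans
#' @export
setGeneric("latentMeans", function(x) standardGeneric("latentMeans"))

#' @rdname dmrMap
#' @export
setGeneric("dmrMap", function(x) standardGeneric("dmrMap"))
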
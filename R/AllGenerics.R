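#' @include utils.R
NULL

#' @export
setGeneric("txId", function(x) standardGeneric("txId"))

#' @export
setGeneric("isCoding", function(x) standardGeneric("isCoding"))

#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))

#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @export
setGeneric("txRanges", function(x) standardGeneric("txRanges"))

#' @export
setGeneric("exonicLength", function(x) standardGeneric("exonicLength"))

#' @export
setGeneric("filterNoncoding", function(x) standardGeneric("filterNoncoding"))

#' @export
setGeneric("promoterWindows", function(x, layout, ...)
  standardGeneric("promoterWindows"))

#' @export
setGeneric("rpkm", function(x, ...) standardGeneric("rpkm"))

#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))

#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @export
setGeneric("gridPositions", function(x) standardGeneric("gridPositions"))

#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))

#' @export
setGeneric("clusterMerges", function(x) standardGeneric("clusterMerges"))

#' @export
setGeneric("clusterHeights", function(x) standardGeneric("clusterHeights"))
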
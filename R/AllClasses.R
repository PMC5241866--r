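#' @include AllGenerics.R
NULL

#' A set of annotated transcript models
#'
#' `TranscriptSet` holds RefSeq-style transcript models: the genomic span and
#' strand of each transcript (as a [GenomicRanges::GRanges]), its exon
#' structure, its accession, and a coding flag derived from the accession
#' prefix (`NR_` marks non-coding RNA). Coordinates are stored 1-based closed
#' internally (the GRanges convention); all readers and writers translate
#' from/to the 0-based half-open BED convention, and the exported arithmetic
#' (promoter windows, report coordinates) is documented in BED coordinates.
#'
#' @slot txId character vector of transcript accessions.
#' @slot ranges `GRanges` of transcript spans, strand set to `+`/`-`.
#' @slot exons `IRangesList`, one element per transcript, absolute exon
#'   intervals sorted and non-overlapping, all within the transcript span.
#' @slot coding logical; `FALSE` for `NR_` accessions.
#' @slot geneSymbol character; gene symbol when the annotation dialect
#'   carries one (refFlat), otherwise `NA`.
#'
#' @seealso [readAnnotation()], [promoterWindows()], [filterNoncoding()]
#' @export
setClass("TranscriptSet",
  slots = c(txId = "character", ranges = "GRanges", exons = "IRangesList",
            coding = "logical", geneSymbol = "character"))

setValidity("TranscriptSet", function(object) {
  n <- length(object@txId)
  if (length(object@ranges) != n || length(object@exons) != n ||
      length(object@coding) != n || length(object@geneSymbol) != n)
    return("slot lengths disagree")
  if (n == 0L) return(TRUE)
  str <- as.character(GenomicRanges::strand(object@ranges))
  if (!all(str %in% c("+", "-")))
    return("strand must be '+' or '-' for every transcript")
  nex <- S4Vectors::elementNROWS(object@exons)
  if (any(nex == 0L)) return("every transcript needs at least one exon")
  ex <- unlist(object@exons, use.names = FALSE)
  grp <- rep(seq_len(n), nex)
  if (any(IRanges::width(ex) <= 0L)) return("exons must have start < end")
  if (any(BiocGenerics::start(ex) < BiocGenerics::start(object@ranges)[grp]) ||
      any(BiocGenerics::end(ex) > BiocGenerics::end(object@ranges)[grp]))
    return("exon blocks outside transcript span")
  same <- grp[-length(grp)] == grp[-1L]
  if (any(same &
          BiocGenerics::start(ex)[-1L] <= BiocGenerics::end(ex)[-length(grp)]))
    return("exons must be sorted and non-overlapping")
  TRUE
})

#' Counts-with-metadata container for RPKM quantification
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `counts`
#' assay (transcripts x samples, non-negative), per-transcript exonic
#' lengths in `rowData(x)$exonLength` and per-sample total mapped reads in
#' `colData(x)$librarySize`. RPKM is derivable via [rpkm()].
#'
#' @seealso [ExpressionMatrix()], [rpkm()], [deCall()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("an assay named 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(!is.finite(cts)) || any(cts < 0))
    return("counts must be finite and non-negative")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("transcript and sample names are required")
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!"exonLength" %in% colnames(rd) || any(rd$exonLength <= 0))
    return("rowData(x)$exonLength must be present and > 0")
  if (!"librarySize" %in% colnames(cd) || any(cd$librarySize <= 0))
    return("colData(x)$librarySize must be present and > 0")
  TRUE
})

#' Orientation-aware ChIP binding-intensity profile for one chromosome
#'
#' At every grid position `p` (multiples of `resolution` anchored at
#' coordinate 0), the count of reads whose 5' end lies within `flank` bp of
#' `p` and whose orientation points toward `p`: forward reads at or upstream
#' of `p`, reverse reads at or downstream of `p`. Boundaries are inclusive
#' on both conditions.
#'
#' @slot chrom chromosome name.
#' @slot resolution grid spacing in bp (default 25 in [bindingProfile()]).
#' @slot flank flanking distance in bp (default 100).
#' @slot counts integer read counts, one per grid position.
#' @slot chromLength chromosome length in bp.
#'
#' @seealso [bindingProfile()], [naivePeakCall()], [writeBedGraph()]
#' @export
setClass("IntensityProfile",
  slots = c(chrom = "character", resolution = "integer", flank = "integer",
            counts = "integer", chromLength = "numeric"))

setValidity("IntensityProfile", function(object) {
  if (length(object@chrom) != 1L) return("chrom must be a single name")
  if (object@resolution < 1L || object@flank < 0L)
    return("resolution must be >= 1 and flank >= 0")
  if (any(object@counts < 0L)) return("profile counts must be >= 0")
  nbins <- length(object@counts)
  if (nbins != length(seq.int(0L, object@chromLength - 1L,
                              by = object@resolution)))
    return("counts length does not match the grid implied by chromLength")
  TRUE
})

#' Result of agglomerative hierarchical clustering
#'
#' Merge structure in the `stats::hclust` encoding: row `k` of `merge` joins
#' two nodes (negative values are leaves, positive values earlier merges) at
#' `height[k]`; `order` is the leaf permutation from a left-before-right
#' traversal in merge order.
#'
#' @slot merge integer matrix, `n-1` rows by 2 columns.
#' @slot height numeric merge heights (`1 - Pearson r` under the default
#'   metric), all `>= 0`.
#' @slot order integer leaf permutation.
#' @slot labels character row labels.
#'
#' @seealso [hcluster()], [as.hclust.ClusterTree()]
#' @export
setClass("ClusterTree",
  slots = c(merge = "matrix", height = "numeric", order = "integer",
            labels = "character"))

setValidity("ClusterTree", function(object) {
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L || length(object@height) != n - 1L)
    return("need exactly n-1 merges for n leaves")
  if (any(object@height < 0)) return("merge heights must be >= 0")
  if (!identical(sort(object@order), seq_len(n)))
    return("order must be a permutation of the leaves")
  TRUE
})

#' Machine-readable record of planted simulation truth
#'
#' Stands in for validated external data: which transcripts were simulated
#' as differentially expressed, TF-bound (promoter window containing a
#' planted binding-site summit), or tissue-restricted, together with the
#' seed and all generator parameters.
#'
#' `boundIds` lists every transcript whose promoter window (under the
#' simulation's own window parameters) contains a planted summit — in dense
#' annotations a summit can fall in overlapping windows of neighbouring
#' transcripts, and each of those is genuinely bound by the method's
#' definition. `hostIds` are the transcripts the summits were sampled for.
#'
#' @slot seed integer seed the generator ran under.
#' @slot params list of all generator parameters, echoed.
#' @slot deIds,deDirection planted differentially expressed transcripts and
#'   their direction (`up`/`down`, named by transcript).
#' @slot boundIds,hostIds,summits TF-binding truth; `summits` is a numeric
#'   vector of 0-based summit coordinates named by host transcript.
#' @slot summitChrom chromosome of each summit, parallel to `summits`.
#' @slot restrictedIds planted tissue-restricted transcripts.
#' @slot targetTissue tissue the restricted transcripts are ON in.
#'
#' @seealso [simulateGenome()], [evaluateRecovery()]
#' @export
setClass("SimTruth",
  slots = c(seed = "integer", params = "list",
            deIds = "character", deDirection = "character",
            boundIds = "character", hostIds = "character",
            summits = "numeric", summitChrom = "character",
            restrictedIds = "character", targetTissue = "character"))

setMethod("show", "TranscriptSet", function(object) {
  cat(sprintf("TranscriptSet with %d transcripts (%d non-coding) on %d chromosome(s)\n",
              length(object@txId), sum(!object@coding),
              length(unique(as.character(GenomicRanges::seqnames(object@ranges))))))
  if (length(object@txId))
    cat("  ids:", paste(utils::head(object@txId, 5L), collapse = ", "),
        if (length(object@txId) > 5L) "..." else "", "\n")
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d transcripts x %d samples\n",
              nrow(object), ncol(object)))
  cat("  samples:", paste(colnames(object), collapse = ", "), "\n")
  cat("  library sizes:",
      paste(format(SummarizedExperiment::colData(object)$librarySize,
                   big.mark = ","), collapse = ", "), "\n")
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile %s: %d bins at %d bp (flank %d bp), max count %d\n",
              object@chrom, length(object@counts), object@resolution,
              object@flank,
              if (length(object@counts)) max(object@counts) else 0L))
})

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree with %d leaves; merge heights in [%.4g, %.4g]\n",
              length(object@labels), min(object@height), max(object@height)))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth (seed %d): %d DE, %d bound (%d hosts), %d restricted\n",
              object@seed, length(object@deIds), length(object@boundIds),
              length(object@hostIds), length(object@restrictedIds)))
})
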
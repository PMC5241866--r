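#' @include AllClasses.R
NULL

#' Construct a TranscriptSet
#'
#' Coordinates are given in the BED convention: 0-based, half-open.
#'
#' @param txId character transcript accessions. Accessions starting with
#'   `NR_` are non-coding by the prefix rule unless `coding` is supplied.
#' @param chrom chromosome of each transcript.
#' @param txStart,txEnd transcript span, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param exons list with one element per transcript, each a two-column
#'   matrix/data.frame of 0-based half-open `(start, end)` exon intervals;
#'   `NULL` means a single exon spanning the transcript.
#' @param coding logical; default derived from the accession prefix.
#' @param geneSymbol optional gene symbols (refFlat annotations carry one).
#' @return A [TranscriptSet-class] object.
#' @examples
#' ts <- TranscriptSet("NR_000001", "chr1", 100, 1100, "+",
#'                     exons = list(cbind(c(100, 800), c(300, 1100))))
#' exonicLength(ts)
#' @export
TranscriptSet <- function(txId, chrom, txStart, txEnd, strand,
                          exons = NULL, coding = NULL, geneSymbol = NULL) {
  txId <- as.character(txId)
  n <- length(txId)
  if (any(txEnd <= txStart))
    .stopf("txStart < txEnd violated for: %s",
           paste(txId[txEnd <= txStart], collapse = ", "))
  if (is.null(exons))
    exons <- lapply(seq_len(n), function(i) cbind(txStart[i], txEnd[i]))
  exl <- IRanges::IRangesList(lapply(exons, function(e) {
    e <- as.matrix(e)
    IRanges::IRanges(start = as.integer(e[, 1L]) + 1L,
                     end = as.integer(e[, 2L]))
  }))
  if (is.null(coding)) coding <- !startsWith(txId, "NR_")
  if (is.null(geneSymbol)) geneSymbol <- rep(NA_character_, n)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(txStart) + 1L,
                              end = as.integer(txEnd)),
    strand = as.character(strand))
  methods::new("TranscriptSet", txId = txId, ranges = gr, exons = exl,
               coding = as.logical(coding),
               geneSymbol = as.character(geneSymbol))
}

#' @describeIn TranscriptSet number of transcripts
#' @param x a `TranscriptSet`
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@txId))

#' @export
setMethod("txId", "TranscriptSet", function(x) x@txId)

#' @export
setMethod("isCoding", "TranscriptSet", function(x) x@coding)

#' @export
setMethod("geneSymbol", "TranscriptSet", function(x) x@geneSymbol)

#' @export
setMethod("exonRanges", "TranscriptSet", function(x) {
  out <- x@exons
  names(out) <- x@txId
  out
})

#' Transcript spans as a GRanges
#'
#' Returns the transcript spans with `txId`, `coding` and `geneSymbol`
#' metadata columns.
#' @param x a `TranscriptSet`
#' @export
setMethod("txRanges", "TranscriptSet", function(x) {
  gr <- x@ranges
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    txId = x@txId, coding = x@coding, geneSymbol = x@geneSymbol)
  names(gr) <- x@txId
  gr
})

#' Summed exon length per transcript
#'
#' The "per kilobase of transcript" denominator of RPKM is the exonic
#' (mature-transcript) length, not the genomic span.
#' @param x a `TranscriptSet`
#' @return named integer vector of exonic lengths in bp.
#' @export
setMethod("exonicLength", "TranscriptSet", function(x) {
  stats::setNames(as.integer(sum(IRanges::width(x@exons))), x@txId)
})

setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@txId)
  methods::new("TranscriptSet", txId = x@txId[i], ranges = x@ranges[i],
               exons = x@exons[i], coding = x@coding[i],
               geneSymbol = x@geneSymbol[i])
})

#' Keep only non-coding transcripts
#'
#' Retains exactly the transcripts whose accession marks them as non-coding
#' RNA (RefSeq `NR_` prefix), preserving order. This is the first gate of
#' the lncRNA discovery pipeline.
#' @param x a `TranscriptSet`
#' @return the non-coding subset, order preserved.
#' @export
setMethod("filterNoncoding", "TranscriptSet", function(x) x[!x@coding])

#' Strand-aware promoter windows
#'
#' Builds the window from `upstream` bp upstream to `downstream` bp
#' downstream of each transcript's start site. With `strandAware = TRUE`
#' (default) the start site is `txStart` on the `+` strand and `txEnd` on
#' the `-` strand, and "upstream" follows the strand: a `+` transcript with
#' 0-based start S gets `[S - upstream, S + downstream)`; a `-` transcript
#' with 0-based end E gets `[E - downstream, E + upstream)`. Windows are
#' clipped to the chromosome; a window that is empty after clipping is an
#' error, never silently dropped.
#'
#' @param x a [TranscriptSet-class].
#' @param layout named numeric vector of chromosome lengths in bp (a
#'   "genome layout", see [readChromSizes()]).
#' @param upstream,downstream window extent in bp (defaults 5000 and 500,
#'   the regulatory-assignment window used throughout the pipeline).
#' @param strandAware if `FALSE`, anchor at `txStart` regardless of strand.
#' @return `GRanges` of windows named by transcript id, strand copied.
#' @examples
#' ts <- TranscriptSet("NR_000001", "chr1", 10000, 12000, "+")
#' promoterWindows(ts, c(chr1 = 1e6))  # BED interval [5000, 10500)
#' @export
setMethod("promoterWindows", "TranscriptSet",
  function(x, layout, upstream = 5000, downstream = 500, strandAware = TRUE) {
    if (upstream < 0 || downstream < 0 || (upstream == 0 && downstream == 0))
      .stopf("upstream and downstream must be >= 0 and not both 0")
    chrom <- as.character(GenomicRanges::seqnames(x@ranges))
    bad <- !(chrom %in% names(layout))
    if (any(bad))
      .stopf("chromosome(s) absent from layout: %s",
             paste(unique(chrom[bad]), collapse = ", "))
    s0 <- BiocGenerics::start(x@ranges) - 1L
    e0 <- BiocGenerics::end(x@ranges)
    str <- as.character(GenomicRanges::strand(x@ranges))
    minus <- strandAware & str == "-"
    tss <- ifelse(minus, e0, s0)
    w0 <- ifelse(minus, tss - downstream, tss - upstream)
    w1 <- ifelse(minus, tss + upstream, tss + downstream)
    len <- unname(layout[chrom])
    w0c <- pmax(w0, 0)
    w1c <- pmin(w1, len)
    if (any(w1c <= w0c))
      .stopf("promoter window empty after clipping to the chromosome for: %s",
             paste(x@txId[w1c <= w0c], collapse = ", "))
    out <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = w0c + 1L, end = w1c),
      strand = str, txId = x@txId)
    names(out) <- x@txId
    out
  })

#' Read a transcript annotation (BED12 or refFlat)
#'
#' BED12 block fields are expanded to absolute exon intervals; refFlat
#' (geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds) is converted to the same internal
#' representation. Coding status comes from the accession prefix only:
#' everything not starting `NR_` is treated as coding. Malformed lines
#' raise an error naming the line number.
#'
#' @param path annotation file.
#' @param dialect `"bed12"` (default) or `"refflat"`.
#' @return a [TranscriptSet-class].
#' @export
readAnnotation <- function(path, dialect = c("bed12", "refflat")) {
  dialect <- match.arg(dialect)
  tok <- .tokenizeLines(path)
  n <- length(tok$fields)
  if (n == 0L) .stopf("%s: no annotation records", path)
  txId <- chrom <- strand <- sym <- character(n)
  txStart <- txEnd <- numeric(n)
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    f <- tok$fields[[i]]
    ln <- tok$lineno[i]
    if (dialect == "bed12") {
      if (length(f) < 12L)
        .stopf("line %d: expected 12 BED12 fields, got %d", ln, length(f))
      chrom[i] <- f[1L]
      txStart[i] <- .asNum(f[2L], "chromStart", ln)
      txEnd[i] <- .asNum(f[3L], "chromEnd", ln)
      txId[i] <- f[4L]
      strand[i] <- f[6L]
      nb <- .asNum(f[10L], "blockCount", ln)
      sizes <- .asNum(strsplit(sub(",$", "", f[11L]), ",")[[1L]],
                      "blockSizes", ln)
      starts <- .asNum(strsplit(sub(",$", "", f[12L]), ",")[[1L]],
                       "blockStarts", ln)
      if (length(sizes) != nb || length(starts) != nb)
        .stopf("line %d: blockCount %d disagrees with block lists", ln, nb)
      es <- txStart[i] + starts
      ee <- es + sizes
      sym[i] <- NA_character_
    } else {
      if (length(f) < 11L)
        .stopf("line %d: expected 11 refFlat fields, got %d", ln, length(f))
      sym[i] <- f[1L]
      txId[i] <- f[2L]
      chrom[i] <- f[3L]
      strand[i] <- f[4L]
      txStart[i] <- .asNum(f[5L], "txStart", ln)
      txEnd[i] <- .asNum(f[6L], "txEnd", ln)
      nb <- .asNum(f[9L], "exonCount", ln)
      es <- .asNum(strsplit(sub(",$", "", f[10L]), ",")[[1L]],
                   "exonStarts", ln)
      ee <- .asNum(strsplit(sub(",$", "", f[11L]), ",")[[1L]],
                   "exonEnds", ln)
      if (length(es) != nb || length(ee) != nb)
        .stopf("line %d: exonCount %d disagrees with exon lists", ln, nb)
    }
    if (!strand[i] %in% c("+", "-"))
      .stopf("line %d: strand must be '+' or '-', got '%s'", ln, strand[i])
    if (txEnd[i] <= txStart[i])
      .stopf("line %d: txStart must be < txEnd", ln)
    if (any(ee <= es))
      .stopf("line %d: exon blocks must have positive length", ln)
    if (any(es < txStart[i]) || any(ee > txEnd[i]))
      .stopf("line %d: exon block outside transcript span", ln)
    if (is.unsorted(es, strictly = TRUE) ||
        any(es[-1L] < ee[-length(ee)]))
      .stopf("line %d: exon blocks must be sorted and non-overlapping", ln)
    exons[[i]] <- cbind(es, ee)
  }
  if (anyDuplicated(txId))
    .warnf("duplicated transcript ids in %s: %s", path,
           paste(unique(txId[duplicated(txId)]), collapse = ", "))
  TranscriptSet(txId, chrom, txStart, txEnd, strand, exons,
                geneSymbol = sym)
}

#' Write a TranscriptSet as BED12
#'
#' Emits one BED12 line per transcript (score 0, thickStart = thickEnd =
#' chromStart, itemRgb 0). `readAnnotation(writeAnnotation(x))` round-trips
#' the transcript models exactly; note the gene symbol is not representable
#' in BED12 and is dropped.
#' @param x a [TranscriptSet-class].
#' @param path output file.
#' @export
writeAnnotation <- function(x, path) {
  chrom <- as.character(GenomicRanges::seqnames(x@ranges))
  s0 <- BiocGenerics::start(x@ranges) - 1L
  e0 <- BiocGenerics::end(x@ranges)
  str <- as.character(GenomicRanges::strand(x@ranges))
  blocks <- vapply(seq_along(x@txId), function(i) {
    ex <- x@exons[[i]]
    sizes <- IRanges::width(ex)
    starts <- BiocGenerics::start(ex) - 1L - s0[i]
    sprintf("%d\t%s\t%s", length(sizes),
            paste(sizes, collapse = ","), paste(starts, collapse = ","))
  }, character(1))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%s",
                   chrom, s0, e0, x@txId, str, s0, s0, blocks)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write chromosome sizes
#'
#' Two-column tab-separated file: chromosome name, length in bp. The result
#' is the "genome layout" used for window clipping and profile grids.
#' @param path chrom.sizes file.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (any(tab$length <= 0)) .stopf("%s: chromosome lengths must be > 0", path)
  if (anyDuplicated(tab$chrom))
    .stopf("%s: duplicated chromosome names", path)
  stats::setNames(tab$length, tab$chrom)
}

#' @rdname readChromSizes
#' @param layout named numeric vector of chromosome lengths.
#' @export
writeChromSizes <- function(layout, path) {
  writeLines(sprintf("%s\t%d", names(layout), as.integer(layout)), path)
  invisible(path)
}

#' Write promoter windows (or any named GRanges) as BED6
#'
#' name = transcript id, score = 0, strand copied.
#' @param gr a `GRanges` with names (e.g. from [promoterWindows()]).
#' @param path output file.
#' @export
writeWindowsBed <- function(gr, path) {
  nm <- if (is.null(names(gr))) sprintf("window%d", seq_along(gr)) else names(gr)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                   nm, as.character(GenomicRanges::strand(gr)))
  writeLines(lines, path)
  invisible(path)
}
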
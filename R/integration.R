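#' @include annotation.R chip.R
NULL

#' Classify transcripts as TF-regulated from promoter-window peaks
#'
#' A transcript is considered regulated by the profiled transcription
#' factor iff at least one binding-site peak overlaps its promoter window
#' (default: 5 kb upstream to 0.5 kb downstream of the strand-aware start
#' site). Calls are transcript-level; with `byGene = TRUE`, transcripts
#' sharing a gene symbol are scored against the union of their windows, so
#' a peak in any isoform's window marks the whole gene.
#'
#' @param transcripts a [TranscriptSet-class].
#' @param peaks `GRanges` of peaks ([readPeaks()] or [naivePeakCall()]).
#' @param layout named vector of chromosome lengths.
#' @param upstream,downstream promoter-window extent in bp.
#' @param strandAware anchor the window at the strand-aware start site.
#' @param byGene merge windows of transcripts sharing a gene symbol;
#'   transcripts without a symbol stay transcript-level.
#' @return data.frame with columns `transcript_id`, `tf_bound`,
#'   `n_peaks_in_window`.
#' @export
classifyTfRegulated <- function(transcripts, peaks, layout,
                                upstream = 5000, downstream = 500,
                                strandAware = TRUE, byGene = FALSE) {
  w <- promoterWindows(transcripts, layout, upstream = upstream,
                       downstream = downstream, strandAware = strandAware)
  n <- GenomicRanges::countOverlaps(w, peaks, ignore.strand = TRUE)
  if (byGene) {
    sym <- geneSymbol(transcripts)
    grp <- !is.na(sym)
    if (any(grp)) {
      hit <- n >= 1L
      geneHit <- tapply(hit[grp], sym[grp], any)
      genePeaks <- vapply(split(seq_along(w)[grp], sym[grp]), function(ii) {
        length(unique(S4Vectors::queryHits(
          GenomicRanges::findOverlaps(peaks, w[ii], ignore.strand = TRUE))))
      }, integer(1))
      n[grp] <- genePeaks[sym[grp]]
      hit[grp] <- geneHit[sym[grp]]
      return(data.frame(transcript_id = txId(transcripts), tf_bound = hit,
                        n_peaks_in_window = as.integer(n),
                        row.names = NULL, stringsAsFactors = FALSE))
    }
  }
  data.frame(transcript_id = txId(transcripts), tf_bound = n >= 1L,
             n_peaks_in_window = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect differentially expressed and TF-bound sets
#'
#' The overlap that turns two evidence streams into co-regulation calls:
#' how many differentially expressed transcripts also carry a peak in
#' their promoter window. DE ids absent from the binding classification
#' are warned about and treated as unbound.
#' @param deCalls data.frame from [deCall()].
#' @param bound data.frame from [classifyTfRegulated()].
#' @return list with `n_de`, `n_de_and_bound` and the sorted `ids`.
#' @export
intersectDeWithBound <- function(deCalls, bound) {
  deIds <- deCalls$transcript_id[deCalls$direction != "none"]
  missing <- setdiff(deIds, bound$transcript_id)
  if (length(missing))
    .warnf("%d DE transcript(s) absent from the binding classification; treated as unbound",
           length(missing))
  boundIds <- bound$transcript_id[bound$tf_bound]
  ids <- sort(intersect(deIds, boundIds))
  list(n_de = length(deIds), n_de_and_bound = length(ids), ids = ids)
}

#' Assemble the ranked candidate report
#'
#' One row per transcript combining all evidence: expression gate,
#' differential expression, promoter-window TF binding, and (optionally)
#' tissue restriction. The final `candidate` flag is the conjunction of
#' all supplied evidence. Rows are sorted by `|log2_fc|` descending with
#' infinite fold changes first and ties broken by transcript id, so the
#' report is byte-for-byte reproducible.
#'
#' @param transcripts the [TranscriptSet-class] under analysis (typically
#'   the non-coding subset).
#' @param gateIds ids passing the expression gate ([expressedGate()]).
#' @param deCalls data.frame from [deCall()].
#' @param bound data.frame from [classifyTfRegulated()].
#' @param layout named vector of chromosome lengths.
#' @param restriction optional named logical from [tissueRestriction()];
#'   when supplied, candidacy additionally requires restriction.
#' @param upstream,downstream,strandAware window parameters echoed into
#'   the report coordinates (must match the classification).
#' @return data.frame with columns `transcript_id`, `chrom`, `strand`,
#'   `tss`, `window_start`, `window_end`, `expressed`, `log2_fc`,
#'   `de_direction`, `n_peaks_in_window`, `tf_bound`, `tissue_restricted`,
#'   `candidate`. Coordinates are 0-based half-open (BED convention); the
#'   start site of a `-` strand transcript is reported as its half-open
#'   transcript end.
#' @export
candidateReport <- function(transcripts, gateIds, deCalls, bound, layout,
                            restriction = NULL, upstream = 5000,
                            downstream = 500, strandAware = TRUE) {
  ids <- txId(transcripts)
  w <- promoterWindows(transcripts, layout, upstream = upstream,
                       downstream = downstream, strandAware = strandAware)
  s0 <- BiocGenerics::start(transcripts@ranges) - 1L
  e0 <- BiocGenerics::end(transcripts@ranges)
  str <- as.character(GenomicRanges::strand(transcripts@ranges))
  tss <- ifelse(strandAware & str == "-", e0, s0)
  dm <- match(ids, deCalls$transcript_id)
  lfc <- deCalls$log2_fc[dm]
  dir <- deCalls$direction[dm]
  dir[is.na(dir)] <- "none"
  lfc[is.na(lfc)] <- 0
  bm <- match(ids, bound$transcript_id)
  if (anyNA(bm))
    .warnf("%d transcript(s) absent from the binding classification; treated as unbound",
           sum(is.na(bm)))
  nPeaks <- ifelse(is.na(bm), 0L, bound$n_peaks_in_window[bm])
  tfBound <- ifelse(is.na(bm), FALSE, bound$tf_bound[bm])
  restricted <- if (is.null(restriction)) rep(NA, length(ids)) else
    unname(restriction[ids]) %in% TRUE
  candidate <- ids %in% gateIds & dir != "none" & tfBound &
    (if (is.null(restriction)) TRUE else restricted)
  out <- data.frame(
    transcript_id = ids,
    chrom = as.character(GenomicRanges::seqnames(transcripts@ranges)),
    strand = str,
    tss = as.integer(tss),
    window_start = BiocGenerics::start(w) - 1L,
    window_end = BiocGenerics::end(w),
    expressed = ids %in% gateIds,
    log2_fc = lfc,
    de_direction = dir,
    n_peaks_in_window = as.integer(nPeaks),
    tf_bound = tfBound,
    tissue_restricted = if (is.null(restriction)) NA else restricted,
    candidate = candidate,
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-abs(out$log2_fc), out$transcript_id), , drop = FALSE]
}

#' @rdname candidateReport
#' @param report a candidate report data.frame.
#' @param path output TSV (floats carry 6 significant digits).
#' @export
writeCandidateReport <- function(report, path) {
  fmt <- report
  fmt$log2_fc <- .fmtNum(report$log2_fc)
  lines <- c(paste(colnames(fmt), collapse = "\t"),
             do.call(paste, c(lapply(fmt, as.character), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname candidateReport
#' @export
readCandidateReport <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "",
                           colClasses = c(transcript_id = "character",
                                          chrom = "character",
                                          strand = "character"))
  tab$log2_fc <- as.numeric(tab$log2_fc)
  tab
}
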
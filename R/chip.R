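#' @include AllClasses.R
NULL

## Internal representation of ChIP reads: a GRanges of width-1 anchors at
## the read 5' end (the conventional anchor for directional read counting),
## strand '+'/'-'. Uniqueness of alignment is an upstream responsibility.

#' Read uniquely-aligned ChIP reads from BED6
#'
#' Each record is reduced to (chromosome, 5' end, strand): the 5' end is
#' `chromStart` for `+` reads and `chromEnd - 1` for `-` reads. A missing
#' or unstranded record is an error — orientation is what the binding
#' profile measures.
#' @param path BED6 file.
#' @return `GRanges` of width-1 5'-end anchors with a `name` column.
#' @seealso [bindingProfile()], [dedupReads()]
#' @export
readChipBed <- function(path) {
  tok <- .tokenizeLines(path)
  n <- length(tok$fields)
  chrom <- strand <- nm <- character(n)
  pos5 <- numeric(n)
  for (i in seq_len(n)) {
    f <- tok$fields[[i]]
    ln <- tok$lineno[i]
    if (length(f) < 6L)
      .stopf("line %d: BED6 with a strand column is required", ln)
    if (!f[6L] %in% c("+", "-"))
      .stopf("line %d: missing or invalid strand '%s'", ln, f[6L])
    s <- .asNum(f[2L], "chromStart", ln)
    e <- .asNum(f[3L], "chromEnd", ln)
    if (e <= s) .stopf("line %d: chromStart must be < chromEnd", ln)
    chrom[i] <- f[1L]
    nm[i] <- f[4L]
    strand[i] <- f[6L]
    pos5[i] <- if (f[6L] == "+") s else e - 1
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos5 + 1, width = 1L),
                         strand = strand, name = nm)
}

#' Write ChIP read anchors as BED6
#'
#' Reads are written with a nominal `readLength` so standard browsers can
#' display them; [readChipBed()] recovers the identical 5'-end anchors.
#' @param reads `GRanges` of 5'-end anchors.
#' @param path output file.
#' @param readLength nominal read length in bp (default 36).
#' @export
writeChipBed <- function(reads, path, readLength = 36L) {
  p0 <- BiocGenerics::start(reads) - 1L
  str <- as.character(GenomicRanges::strand(reads))
  s <- ifelse(str == "+", p0, p0 - readLength + 1L)
  e <- s + readLength
  nm <- S4Vectors::mcols(reads)$name
  if (is.null(nm)) nm <- sprintf("read%d", seq_along(reads))
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     as.character(GenomicRanges::seqnames(reads)),
                     as.integer(s), as.integer(e), nm, str),
             path)
  invisible(path)
}

#' Collapse duplicate read anchors
#'
#' Keeps one read per (chromosome, 5' end, strand) triple. Duplicates are
#' kept by default throughout the package; this implements the optional
#' deduplication switch.
#' @param reads `GRanges` of 5'-end anchors.
#' @export
dedupReads <- function(reads) {
  key <- paste(as.character(GenomicRanges::seqnames(reads)),
               BiocGenerics::start(reads),
               as.character(GenomicRanges::strand(reads)))
  reads[!duplicated(key)]
}

#' Orientation-aware binding-intensity profile
#'
#' For every grid position `p` (multiples of `resolution` from 0, last
#' point below the chromosome length) counts the reads oriented toward `p`
#' within `flank` bp: forward reads with `pos5 <= p` and `p - pos5 <=
#' flank`, reverse reads with `pos5 >= p` and `pos5 - p <= flank`, both
#' boundaries inclusive. Around a true binding site the forward cluster
#' upstream and the reverse cluster downstream both point inward, so the
#' profile forms its maximum plateau between them (the strand cross).
#'
#' Implemented with per-strand cumulative coverage sums, O(genome + reads).
#'
#' @param reads `GRanges` of 5'-end anchors (see [readChipBed()]).
#' @param layout named vector of chromosome lengths.
#' @param resolution grid spacing in bp (default 25).
#' @param flank flanking distance in bp (default 100).
#' @return named list of [IntensityProfile-class], one per layout
#'   chromosome.
#' @export
bindingProfile <- function(reads, layout, resolution = 25L, flank = 100L) {
  resolution <- as.integer(resolution)
  flank <- as.integer(flank)
  if (resolution < 1L || flank < 0L)
    .stopf("resolution must be >= 1 and flank >= 0")
  chrom <- as.character(GenomicRanges::seqnames(reads))
  bad <- setdiff(unique(chrom), names(layout))
  if (length(bad))
    .stopf("reads on chromosome(s) absent from layout: %s",
           paste(bad, collapse = ", "))
  p0 <- BiocGenerics::start(reads) - 1L
  if (any(p0 < 0) || any(p0 >= layout[chrom]))
    .stopf("read 5' ends must lie within their chromosome")
  str <- as.character(GenomicRanges::strand(reads))
  out <- lapply(names(layout), function(ch) {
    L <- as.integer(layout[[ch]])
    grid0 <- seq.int(0L, L - 1L, by = resolution)
    onch <- chrom == ch
    csF <- c(0, cumsum(tabulate(p0[onch & str == "+"] + 1L, nbins = L)))
    csR <- c(0, cumsum(tabulate(p0[onch & str == "-"] + 1L, nbins = L)))
    ## cs[k + 1] = number of read 5' ends at positions < k
    countIn <- function(cs, a, b) {
      a <- pmax(a, 0L); b <- pmin(b, L - 1L)
      pmax(cs[b + 2L] - cs[a + 1L], 0)
    }
    fwd <- countIn(csF, grid0 - flank, grid0)
    rev <- countIn(csR, grid0, grid0 + flank)
    methods::new("IntensityProfile", chrom = ch, resolution = resolution,
                 flank = flank, counts = as.integer(fwd + rev),
                 chromLength = as.numeric(L))
  })
  names(out) <- names(layout)
  out
}

#' @export
setMethod("gridPositions", "IntensityProfile", function(x)
  (seq_along(x@counts) - 1L) * x@resolution)

#' @export
setMethod("profileCounts", "IntensityProfile", function(x) x@counts)

.profileList <- function(x) {
  if (methods::is(x, "IntensityProfile")) return(list(x))
  if (!is.list(x) || !all(vapply(x, methods::is, logical(1), "IntensityProfile")))
    .stopf("expected an IntensityProfile or a list of them")
  x
}

#' Write binding profiles as a bedGraph track
#'
#' UCSC bedGraph dialect: intervals `[p, p + resolution)` with their
#' count, zero runs omitted, sorted by chromosome then position. With
#' `mergeRuns = TRUE` adjacent bins with equal counts collapse into one
#' interval. No track line unless `trackLine = TRUE`.
#' @param profiles an [IntensityProfile-class] or list of them.
#' @param path output file.
#' @param mergeRuns merge adjacent equal-valued bins.
#' @param trackLine emit a `track type=bedGraph` header.
#' @export
writeBedGraph <- function(profiles, path, mergeRuns = FALSE,
                          trackLine = FALSE) {
  profiles <- .profileList(profiles)
  profiles <- profiles[order(vapply(profiles, function(p) p@chrom,
                                    character(1)))]
  lines <- character(0)
  if (trackLine) lines <- "track type=bedGraph"
  for (p in profiles) {
    v <- p@counts
    if (!length(v)) next
    pos0 <- gridPositions(p)
    if (mergeRuns) {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      nz <- r$values > 0L
      if (!any(nz)) next
      s <- pos0[starts[nz]]
      e <- pmin(pos0[ends[nz]] + p@resolution, p@chromLength)
      lines <- c(lines, sprintf("%s\t%d\t%d\t%d", p@chrom, as.integer(s),
                                as.integer(e), r$values[nz]))
    } else {
      nz <- v > 0L
      if (!any(nz)) next
      s <- pos0[nz]
      e <- pmin(s + p@resolution, p@chromLength)
      lines <- c(lines, sprintf("%s\t%d\t%d\t%d", p@chrom, as.integer(s),
                                as.integer(e), v[nz]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read binding-site peaks from BED
#'
#' Peaks called upstream (e.g. by a dedicated ChIP-seq peak caller) are
#' consumed as plain intervals: >= 3 columns, score from column 5 when
#' present (else 0), `source` marked `"external"`.
#' @param path BED file with >= 3 columns.
#' @return `GRanges` with `name`, `score` and `source` columns.
#' @export
readPeaks <- function(path) {
  tok <- .tokenizeLines(path)
  n <- length(tok$fields)
  chrom <- nm <- character(n)
  s <- e <- score <- numeric(n)
  for (i in seq_len(n)) {
    f <- tok$fields[[i]]
    ln <- tok$lineno[i]
    if (length(f) < 3L)
      .stopf("line %d: at least 3 BED columns are required", ln)
    chrom[i] <- f[1L]
    s[i] <- .asNum(f[2L], "chromStart", ln)
    e[i] <- .asNum(f[3L], "chromEnd", ln)
    if (e[i] <= s[i])
      .stopf("line %d: inverted or empty interval [%g, %g)", ln, s[i], e[i])
    nm[i] <- if (length(f) >= 4L) f[4L] else sprintf("peak%d", i)
    score[i] <- if (length(f) >= 5L) .asNum(f[5L], "score", ln) else 0
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = s + 1, end = e),
                         name = nm, score = score, source = "external")
}

#' @rdname readPeaks
#' @param peaks `GRanges` of peaks to write (BED5).
#' @export
writePeaks <- function(peaks, path) {
  nm <- S4Vectors::mcols(peaks)$name
  if (is.null(nm)) nm <- sprintf("peak%d", seq_along(peaks))
  sc <- S4Vectors::mcols(peaks)$score
  if (is.null(sc)) sc <- rep(0, length(peaks))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s",
                     as.character(GenomicRanges::seqnames(peaks)),
                     BiocGenerics::start(peaks) - 1L, BiocGenerics::end(peaks),
                     nm, .fmtNum(sc)),
             path)
  invisible(path)
}

#' Naive Poisson peak caller on a binding profile
#'
#' A deliberately simple fallback so the pipeline can run end-to-end when
#' only aligned reads — not externally called peaks — are available; its
#' peaks are labelled `source = "naive"` so they are never confused with a
#' dedicated caller's output. The background rate `lambda` is the mean grid
#' count over the chromosome; a bin with count `c` is significant when the
#' upper Poisson tail `P(X >= c; lambda)` falls below the significance
#' level, and at least `minRunBins` consecutive significant bins merge into
#' one peak scored by the maximum bin count.
#'
#' Because the per-bin test repeats over tens of thousands of bins, the
#' default applies a per-chromosome Bonferroni correction (level `pCutoff /
#' n_bins`); `correction = "none"` tests every bin at `pCutoff` directly.
#'
#' @param profiles an [IntensityProfile-class] or list of them.
#' @param pCutoff significance level (default 0.05).
#' @param minRunBins minimum run of consecutive significant bins (default 2).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return `GRanges` of peaks with `name`, `score`, `source = "naive"`.
#' @export
naivePeakCall <- function(profiles, pCutoff = 0.05, minRunBins = 2L,
                          correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  profiles <- .profileList(profiles)
  chrom <- nm <- character(0)
  ps <- pe <- sc <- numeric(0)
  for (p in profiles) {
    v <- p@counts
    if (!length(v)) .stopf("empty profile for %s", p@chrom)
    lam <- mean(v)
    alpha <- if (correction == "bonferroni") pCutoff / length(v) else pCutoff
    sig <- stats::ppois(v - 1L, lam, lower.tail = FALSE) < alpha
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= minRunBins)
    if (!length(runs)) next
    pos0 <- gridPositions(p)
    chrom <- c(chrom, rep(p@chrom, length(runs)))
    nm <- c(nm, sprintf("naive_%s_%d", p@chrom, seq_along(runs)))
    ps <- c(ps, pos0[starts[runs]])
    pe <- c(pe, pmin(pos0[ends[runs]] + p@resolution, p@chromLength))
    sc <- c(sc, vapply(runs, function(k) max(v[starts[k]:ends[k]]),
                       integer(1)))
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = ps + 1, end = pe),
                         name = nm, score = as.numeric(sc),
                         source = rep("naive", length(nm)))
}

#' Peaks overlapping a window
#'
#' Keeps peaks sharing at least one base with the window under half-open
#' semantics: `peak.start < window.end` and `window.start < peak.end`.
#' @param peaks `GRanges` of peaks.
#' @param window `GRanges` window(s).
#' @return the overlapping subset of `peaks`.
#' @export
peaksOverlapping <- function(peaks, window) {
  IRanges::subsetByOverlaps(peaks, window, ignore.strand = TRUE)
}
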
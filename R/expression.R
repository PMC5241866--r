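#' @include AllClasses.R
NULL

#' Construct an ExpressionMatrix
#'
#' @param counts non-negative numeric matrix, transcripts x samples, with
#'   dimnames.
#' @param exonLengths exonic transcript lengths in bp; if named, matched to
#'   `rownames(counts)`.
#' @param librarySizes total mapped reads per sample; defaults to the
#'   column sums of `counts`.
#' @return an [ExpressionMatrix-class].
#' @examples
#' m <- matrix(c(100, 0, 50, 10), 2,
#'             dimnames = list(c("NR_1", "NM_1"), c("s1", "s2")))
#' em <- ExpressionMatrix(m, exonLengths = c(2000, 1000),
#'                        librarySizes = c(1e7, 1e7))
#' rpkm(em)
#' @export
ExpressionMatrix <- function(counts, exonLengths, librarySizes = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("counts needs transcript rownames and sample colnames")
  if (!is.null(names(exonLengths))) {
    miss <- setdiff(rownames(counts), names(exonLengths))
    if (length(miss))
      .stopf("no exonic length for: %s", paste(utils::head(miss, 5L),
                                               collapse = ", "))
    exonLengths <- exonLengths[rownames(counts)]
  } else if (length(exonLengths) != nrow(counts)) {
    .stopf("exonLengths must match the number of transcripts")
  }
  if (is.null(librarySizes)) librarySizes <- colSums(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(exonLength = as.numeric(exonLengths),
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(librarySize = as.numeric(librarySizes),
                                   row.names = colnames(counts)))
  methods::new("ExpressionMatrix", se)
}

#' @export
setMethod("exonLengths", "ExpressionMatrix", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$exonLength, rownames(x)))

#' @export
setMethod("librarySizes", "ExpressionMatrix", function(x)
  stats::setNames(SummarizedExperiment::colData(x)$librarySize, colnames(x)))

#' Reads Per Kilobase of transcript per Million mapped reads
#'
#' `rpkm[i, s] = counts[i, s] * 1e9 / (exonLength[i] * librarySize[s])`.
#' The exonic (mature) length is the kilobase denominator; zeros in the
#' counts stay zeros.
#' @param x an [ExpressionMatrix-class].
#' @return numeric matrix with the same dimnames as the counts.
#' @export
setMethod("rpkm", "ExpressionMatrix", function(x) {
  cts <- SummarizedExperiment::assay(x, "counts")
  len <- SummarizedExperiment::rowData(x)$exonLength
  lib <- SummarizedExperiment::colData(x)$librarySize
  cts * 1e9 / outer(len, lib)
})

#' Summed-RPKM expression gate
#'
#' A transcript is carried forward iff its RPKM summed over all samples is
#' strictly greater than `minSummed` (default 1): a row summing to exactly
#' 1.0 is dropped.
#' @param rpkmTable numeric matrix from [rpkm()] (or any transcripts x
#'   samples RPKM table with rownames).
#' @param minSummed strict lower bound on the summed RPKM.
#' @return character vector of retained transcript ids.
#' @export
expressedGate <- function(rpkmTable, minSummed = 1.0) {
  rpkmTable <- as.matrix(rpkmTable)
  if (is.null(rownames(rpkmTable))) .stopf("rpkmTable needs rownames")
  rownames(rpkmTable)[rowSums(rpkmTable) > minSummed]
}

#' Fold-change differential expression call
#'
#' Compares mean RPKM between two disjoint sample sets. `log2_fc =
#' log2(mean_a / mean_b)` with the conventions: both means zero gives 0;
#' exactly one zero gives +/-Inf, which exceeds any threshold. The
#' direction is `up`/`down` when `|log2_fc| >= log2(foldThreshold)`, else
#' `none`. Swapping the conditions negates every finite `log2_fc` exactly.
#'
#' With `test = "binomial"` a p-value is attached from a two-sided exact
#' binomial test of the pooled condition-A count out of the pooled total
#' against the expected proportion `N_a / (N_a + N_b)` of summed library
#' sizes. This is a simple, clearly-labelled significance stand-in, not a
#' dispersion-aware RNA-seq test; the result carries the label in
#' `attr(x, "test")`.
#'
#' @param x an [ExpressionMatrix-class].
#' @param condA,condB character vectors of sample ids (disjoint, non-empty).
#' @param foldThreshold fold-change cutoff (default 2; the alternative 1.5
#'   is a common secondary choice).
#' @param test `"none"` (default) or `"binomial"`.
#' @return data.frame with columns `transcript_id`, `mean_a`, `mean_b`,
#'   `log2_fc`, `direction`, `p_value` (`NA` when `test = "none"`).
#' @export
deCall <- function(x, condA, condB, foldThreshold = 2.0,
                   test = c("none", "binomial")) {
  test <- match.arg(test)
  if (length(condA) == 0L || length(condB) == 0L)
    .stopf("condition sample sets must be non-empty")
  if (length(intersect(condA, condB)))
    .stopf("condition sample sets must be disjoint")
  miss <- setdiff(c(condA, condB), colnames(x))
  if (length(miss)) .stopf("unknown samples: %s", paste(miss, collapse = ", "))
  if (foldThreshold < 1) .stopf("foldThreshold must be >= 1")
  r <- rpkm(x)
  mA <- rowMeans(r[, condA, drop = FALSE])
  mB <- rowMeans(r[, condB, drop = FALSE])
  ## log2(mA) - log2(mB) rather than log2(mA/mB): bitwise-exact negation
  ## under condition swap
  lfc <- ifelse(mA == 0 & mB == 0, 0,
         ifelse(mB == 0, Inf, ifelse(mA == 0, -Inf, log2(mA) - log2(mB))))
  thr <- log2(foldThreshold)
  direction <- ifelse(lfc >= thr & lfc != 0, "up",
               ifelse(lfc <= -thr & lfc != 0, "down", "none"))
  ## at foldThreshold = 1 (thr = 0) a zero log2_fc stays 'none'
  pval <- rep(NA_real_, nrow(r))
  if (test == "binomial") {
    cts <- SummarizedExperiment::assay(x, "counts")
    lib <- librarySizes(x)
    kA <- rowSums(cts[, condA, drop = FALSE])
    kB <- rowSums(cts[, condB, drop = FALSE])
    p0 <- sum(lib[condA]) / (sum(lib[condA]) + sum(lib[condB]))
    pval <- vapply(seq_len(nrow(r)), function(i) {
      n <- kA[i] + kB[i]
      if (n == 0) return(1.0)
      stats::binom.test(round(kA[i]), round(n), p = p0)$p.value
    }, numeric(1))
  }
  out <- data.frame(transcript_id = rownames(r), mean_a = mA, mean_b = mB,
                    log2_fc = lfc, direction = direction, p_value = pval,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "test") <- if (test == "binomial")
    "exact two-sided binomial (stand-in significance test)" else "none"
  out
}

#' Log-transform, mean-centre and normalize rows for clustering
#'
#' Per cell `log2(rpkm + pseudocount)`; per row, subtract the row mean and
#' divide by the root sum of squares, so every surviving row has mean 0 and
#' unit sum of squares. Rows that are constant after centring carry no
#' profile shape and are dropped with a warning; their ids are available in
#' `attr(result, "dropped")`.
#'
#' The pseudocount (default 1) keeps zero RPKM at log 0; classic clustering
#' tools cannot log zeros.
#' @param rpkmTable transcripts x samples RPKM matrix.
#' @param pseudocount added inside the log (default 1).
#' @return normalized matrix with a `dropped` attribute.
#' @export
preprocessForClustering <- function(rpkmTable, pseudocount = 1.0) {
  m <- as.matrix(rpkmTable)
  if (nrow(m) == 0L || ncol(m) == 0L) .stopf("empty RPKM table")
  lg <- log2(m + pseudocount)
  ctr <- lg - rowMeans(lg)
  ss <- sqrt(rowSums(ctr^2))
  drop <- ss < 1e-12
  if (any(drop))
    .warnf("dropping %d constant row(s) before clustering: %s", sum(drop),
           paste(utils::head(rownames(m)[drop], 5L), collapse = ", "))
  out <- ctr[!drop, , drop = FALSE] / ss[!drop]
  attr(out, "dropped") <- rownames(m)[drop]
  out
}

#' Tissue-restriction filter
#'
#' A computable surrogate for a multi-tissue expression screen: a
#' transcript is called restricted to `targetTissue` iff its expression
#' there is at least `minOn` AND at least `minFoldOverOthers` times the
#' maximum over all other tissues (a zero maximum elsewhere passes whenever
#' the target level passes `minOn`).
#' @param tissueRpkm transcripts x tissues expression matrix (>= 2 tissues).
#' @param targetTissue column name of the tissue of interest.
#' @param minOn minimum absolute expression in the target tissue.
#' @param minFoldOverOthers minimum fold over the loudest other tissue.
#' @return named logical vector.
#' @export
tissueRestriction <- function(tissueRpkm, targetTissue, minOn = 1.0,
                              minFoldOverOthers = 5.0) {
  m <- as.matrix(tissueRpkm)
  if (ncol(m) < 2L) .stopf("need at least two tissues")
  if (!targetTissue %in% colnames(m))
    .stopf("unknown tissue: %s", targetTissue)
  tv <- m[, targetTissue]
  others <- m[, setdiff(colnames(m), targetTissue), drop = FALSE]
  mo <- apply(others, 1L, max)
  stats::setNames(tv >= minOn & (mo == 0 | tv >= minFoldOverOthers * mo),
                  rownames(m))
}

#' Read a counts TSV into an ExpressionMatrix
#'
#' The external counts interface: header row of sample ids, first column
#' `transcript_id`. Exonic lengths come from the annotation; library sizes
#' default to column sums unless supplied.
#' @param path counts TSV.
#' @param transcripts a [TranscriptSet-class] providing exonic lengths, or
#'   a named numeric vector of lengths.
#' @param librarySizes optional named vector of totals per sample.
#' @return an [ExpressionMatrix-class].
#' @export
readCounts <- function(path, transcripts, librarySizes = NULL) {
  m <- readTsvMatrix(path)
  lens <- if (methods::is(transcripts, "TranscriptSet"))
    exonicLength(transcripts) else transcripts
  ExpressionMatrix(m, exonLengths = lens, librarySizes = librarySizes)
}

#' @rdname readCounts
#' @param x an `ExpressionMatrix` to write.
#' @export
writeCounts <- function(x, path) {
  writeTsvMatrix(SummarizedExperiment::assay(x, "counts"), path)
}
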
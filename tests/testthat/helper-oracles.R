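# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (plain loops over the definitions) so they share no
# code path with the package implementations they check.

# count of reads oriented toward each position within `flank` bp
bruteProfile <- function(pos5, strand, positions, flank) {
  vapply(positions, function(p) {
    as.numeric(sum((strand == "+" & pos5 <= p & p - pos5 <= flank) |
                   (strand == "-" & pos5 >= p & pos5 - p <= flank)))
  }, numeric(1))
}

# all-pairs half-open interval overlap count per window (0-based coords)
bruteWindowPeakCounts <- function(pkChrom, pkStart, pkEnd,
                                  wChrom, wStart, wEnd) {
  vapply(seq_along(wStart), function(i) {
    as.numeric(sum(pkChrom == wChrom[i] & pkStart < wEnd[i] &
                   wStart[i] < pkEnd))
  }, numeric(1))
}

# 0-based half-open promoter window from first principles
bruteWindow <- function(txStart, txEnd, strand, upstream, downstream, L) {
  if (strand == "+") w <- c(txStart - upstream, txStart + downstream)
  else w <- c(txEnd - downstream, txEnd + upstream)
  c(max(w[1], 0), min(w[2], L))
}

# average-linkage agglomeration recomputed from the base distance matrix
# over cluster members at every step (no Lance-Williams update), with the
# same deterministic tie rule: clusters in creation order, smallest (i, j)
bruteAvgLinkage <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- length(members)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      d <- mean(D[members[[i]], members[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    merge[s, ] <- c(code[i], code[j])
    height[s] <- max(best[1], 0)
    members <- c(members[-c(i, j)], list(c(members[[i]], members[[j]])))
    code <- c(code[-c(i, j)], s)
  }
  list(merge = merge, height = height)
}

# two-sided exact binomial p-value by direct summation of the mass
# function (minlike rule, the classical two-sided definition), computed
# from log-binomial coefficients
bruteBinomTwoSided <- function(k, n, p) {
  i <- 0:n
  mass <- exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p))
  sum(mass[mass <= mass[k + 1] * (1 + 1e-7)])
}

# random non-overlapping transcripts for property tests (0-based coords)
randomTranscriptSet <- function(n, L, seed, chrom = "chr1") {
  set.seed(seed)
  slot <- floor((L - 16000) / n)
  stopifnot(slot > 600)
  span <- sample(200:(slot - 100), n, replace = TRUE)
  s <- 8000 + (seq_len(n) - 1L) * slot +
    vapply(slot - span, function(g) sample.int(g, 1L), integer(1)) - 1L
  TranscriptSet(sprintf("NR_%06d", seq_len(n)), chrom, s, s + span,
                sample(c("+", "-"), n, replace = TRUE))
}

# IntensityProfile built directly from a counts vector
mkProfile <- function(counts, chrom = "chr1", resolution = 25L,
                      flank = 100L, chromLength = length(counts) * 25) {
  methods::new("IntensityProfile", chrom = chrom,
               resolution = as.integer(resolution),
               flank = as.integer(flank), counts = as.integer(counts),
               chromLength = as.numeric(chromLength))
}

# GRanges of 5'-end read anchors from 0-based positions
mkReads <- function(chrom, pos5, strand) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = pos5 + 1, width = 1L),
                         strand = strand,
                         name = sprintf("r%d", seq_along(pos5)))
}

# GRanges peaks from 0-based half-open intervals
mkPeaks <- function(chrom, start0, end0, score = 0) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1, end = end0),
                         name = sprintf("p%d", seq_along(start0)),
                         score = rep_len(score, length(start0)),
                         source = "external")
}
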
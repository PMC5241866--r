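#' @include annotation.R expression.R chip.R integration.R
NULL

#' Simulate a genome annotation with planted-truth skeleton
#'
#' Generates non-overlapping transcripts on random strands across
#' `nChroms` chromosomes, each with 1-4 exons, accessions `NR_%06d` /
#' `NM_%06d` according to a Bernoulli coding flag. Transcripts are placed
#' in equal slots at least 6 kb from chromosome ends so no promoter window
#' is ever truncated. Deterministic given the seed.
#'
#' @param nChroms number of chromosomes (default 2).
#' @param chromLen chromosome length in bp (default 1e6).
#' @param nTranscripts total transcripts (default 200).
#' @param fracNoncoding probability a transcript is non-coding (default
#'   0.5; realized counts are binomial around it).
#' @param exonsRange integer range of exons per transcript (default 1:4).
#' @param seed RNG seed (mandatory; all generators are pure functions of
#'   parameters and seed).
#' @return list with `transcripts` ([TranscriptSet-class]), `layout`
#'   (named lengths) and `truth` (a [SimTruth-class] skeleton echoing the
#'   parameters).
#' @export
simulateGenome <- function(nChroms = 2L, chromLen = 1e6, nTranscripts = 200L,
                           fracNoncoding = 0.5, exonsRange = 1:4, seed) {
  if (nChroms < 1L || chromLen <= 0 || nTranscripts < 1L)
    .stopf("simulation parameters must be positive")
  margin <- 6000
  perChrom <- ceiling(nTranscripts / nChroms)
  slot <- floor((chromLen - 2 * margin) / perChrom)
  if (slot < 1000)
    .stopf("cannot pack %d transcripts into %d chromosome(s) of %g bp; increase chromLen",
           nTranscripts, nChroms, chromLen)
  withSeed(seed, {
    chromIdx <- rep(seq_len(nChroms), length.out = nTranscripts)
    slotIdx <- unlist(lapply(tabulate(chromIdx, nChroms), seq_len))
    ## transcripts are laid down chromosome-major in slot order
    ord <- order(chromIdx)
    chromIdx <- chromIdx[ord]
    maxSpan <- min(5000, slot - 200)
    span <- round(stats::runif(nTranscripts, 800, maxSpan))
    slotStart <- margin + (slotIdx - 1) * slot
    txStart <- slotStart +
      round(stats::runif(nTranscripts, 0, slot - span - 1))
    txEnd <- txStart + span
    strand <- sample(c("+", "-"), nTranscripts, replace = TRUE)
    coding <- stats::runif(nTranscripts) >= fracNoncoding
    txId <- ifelse(coding, sprintf("NM_%06d", seq_len(nTranscripts)),
                   sprintf("NR_%06d", seq_len(nTranscripts)))
    nEx <- sample(exonsRange, nTranscripts, replace = TRUE)
    exons <- lapply(seq_len(nTranscripts), function(i) {
      k <- nEx[i]
      if (k == 1L) return(cbind(txStart[i], txEnd[i]))
      cuts <- sort(sample(seq_len(span[i] - 1L), 2L * k - 2L))
      b <- c(0, cuts, span[i])
      es <- txStart[i] + b[seq(1L, 2L * k - 1L, by = 2L)]
      ee <- txStart[i] + b[seq(2L, 2L * k, by = 2L)]
      cbind(es, ee)
    })
    layout <- stats::setNames(rep(chromLen, nChroms),
                              sprintf("chr%d", seq_len(nChroms)))
    ts <- TranscriptSet(txId, sprintf("chr%d", chromIdx), txStart, txEnd,
                        strand, exons, coding = coding,
                        geneSymbol = sub("^N[RM]_", "gene", txId))
    truth <- methods::new("SimTruth", seed = as.integer(seed),
      params = list(nChroms = nChroms, chromLen = chromLen,
                    nTranscripts = nTranscripts,
                    fracNoncoding = fracNoncoding),
      deIds = character(0), deDirection = character(0),
      boundIds = character(0), hostIds = character(0),
      summits = numeric(0), summitChrom = character(0),
      restrictedIds = character(0), targetTissue = character(0))
    list(transcripts = ts, layout = layout, truth = truth)
  })
}

#' Simulate a differentiation time-course count matrix
#'
#' Emulates a multi-time-point RNA-seq experiment (one library per time
#' point, as in a 0 h / 60 h / 5 d / 7 d differentiation series): baseline
#' relative abundances are log-normal; a planted fraction of *non-coding*
#' transcripts is differentially expressed, multiplying the last half of
#' the time points by `fold` (up) or `1/fold` (down), split evenly; counts
#' are negative-binomial with a shared dispersion (`nbDispersion = 0`
#' falls back to Poisson). Library sizes are the realized column sums.
#' Non-coding hosts are used because the coding transcripts exist to
#' exercise the accession filter, not to carry signal.
#'
#' @param transcripts [TranscriptSet-class] from [simulateGenome()].
#' @param nTimepoints number of time points (>= 2, default 4).
#' @param depth nominal reads per library (default 1e6).
#' @param nbDispersion negative-binomial dispersion (default 0.1).
#' @param deFrac fraction of `length(transcripts)` planted as DE among the
#'   non-coding transcripts (default 0.15).
#' @param fold planted fold change (default 4).
#' @param baselineMeanlog,baselineSdlog log-normal baseline abundance
#'   parameters (defaults `log(50)` and 1.2 — a realistic dynamic range
#'   that keeps essentially all transcripts above the expression gate).
#' @param seed RNG seed.
#' @return list with `expression` (an [ExpressionMatrix-class]), `deIds`,
#'   and `deDirection` (named by transcript).
#' @export
simulateExpression <- function(transcripts, nTimepoints = 4L, depth = 1e6,
                               nbDispersion = 0.1, deFrac = 0.15,
                               fold = 4.0, baselineMeanlog = log(50),
                               baselineSdlog = 1.2, seed) {
  if (nTimepoints < 2L) .stopf("need at least 2 time points")
  ids <- txId(transcripts)
  nc <- ids[!isCoding(transcripts)]
  nDe <- round(deFrac * length(ids))
  if (nDe > length(nc))
    .stopf("deFrac asks for %d DE transcripts but only %d are non-coding",
           nDe, length(nc))
  withSeed(seed, {
    base <- stats::rlnorm(length(ids), baselineMeanlog, baselineSdlog)
    deIds <- sort(sample(nc, nDe))
    up <- deIds[seq_len(ceiling(nDe / 2))]
    down <- setdiff(deIds, up)
    late <- seq.int(floor(nTimepoints / 2) + 1L, nTimepoints)
    eff <- matrix(1, length(ids), nTimepoints, dimnames = list(ids, NULL))
    eff[match(up, ids), late] <- fold
    eff[match(down, ids), late] <- 1 / fold
    mu <- base * eff * (depth / sum(base))
    counts <- matrix(0, length(ids), nTimepoints)
    for (t in seq_len(nTimepoints)) {
      counts[, t] <- if (nbDispersion > 0)
        stats::rnbinom(length(ids), mu = mu[, t], size = 1 / nbDispersion)
      else stats::rpois(length(ids), mu[, t])
    }
    samples <- if (nTimepoints == 4L) c("t0h", "t60h", "t5d", "t7d")
      else sprintf("tp%d", seq_len(nTimepoints))
    dimnames(counts) <- list(ids, samples)
    lib <- pmax(colSums(counts), 1)
    em <- ExpressionMatrix(counts, exonLengths = exonicLength(transcripts),
                           librarySizes = lib)
    dir <- stats::setNames(c(rep("up", length(up)), rep("down", length(down))),
                           c(up, down))
    list(expression = em, deIds = deIds, deDirection = dir[deIds])
  })
}

#' Simulate ChIP reads with planted strand-shifted binding sites
#'
#' For each planted site a summit is drawn inside the host's promoter
#' window (shrunk by `shift + 4 * posSd` so all reads stay inside);
#' `readsPerSite/2` forward reads are placed at `Normal(summit - shift,
#' posSd)` and the rest as reverse reads at `Normal(summit + shift,
#' posSd)`, rounded and clipped — the inward-pointing cluster geometry the
#' orientation-aware profile detects. Uniform random-strand background is
#' added at `backgroundPerKb` reads per kb per chromosome. Hosts are
#' sampled from the non-coding transcripts (the discovery substrate).
#'
#' The returned `boundIds` list *every* transcript whose promoter window
#' contains a planted summit: in a dense annotation neighbouring windows
#' overlap, and a transcript with a summit in its window is genuinely
#' bound by the method's definition even if it was not the sampled host.
#'
#' @param transcripts,layout from [simulateGenome()].
#' @param boundFrac fraction of `length(transcripts)` given a planted site
#'   (default 0.1).
#' @param readsPerSite reads per planted site (default 60).
#' @param shift distance from summit to each strand cluster (default 75 bp,
#'   placing the clusters ~150 bp apart — the scale the 100-bp flank
#'   statistic is most sensitive to).
#' @param posSd s.d. of read placement around each cluster (default 15).
#' @param backgroundPerKb uniform background reads per kb (default 1).
#' @param upstream,downstream the simulation's own promoter-window
#'   parameters (defaults match the pipeline: 5000 / 500).
#' @param readLength nominal read length; 5' positions are kept
#'   `readLength` bp clear of chromosome ends so BED round-trips exactly.
#' @param seed RNG seed.
#' @return list with `reads` (`GRanges` anchors), `boundIds`, `hostIds`,
#'   `summits` (0-based, named by host) and `summitChrom`.
#' @export
simulateChip <- function(transcripts, layout, boundFrac = 0.1,
                         readsPerSite = 60L, shift = 75L, posSd = 15,
                         backgroundPerKb = 1.0, upstream = 5000,
                         downstream = 500, readLength = 36L, seed) {
  ids <- txId(transcripts)
  nc <- ids[!isCoding(transcripts)]
  nSites <- round(boundFrac * length(ids))
  if (nSites > length(nc))
    .stopf("boundFrac asks for %d sites but only %d non-coding hosts exist",
           nSites, length(nc))
  margin <- shift + 4 * posSd
  w <- promoterWindows(transcripts, layout, upstream = upstream,
                       downstream = downstream)
  if (any(IRanges::width(w) < 2 * margin + 2))
    .stopf("promoter windows too small to contain summit +/- %d bp", margin)
  withSeed(seed, {
    hosts <- sort(sample(nc, nSites))
    hi <- match(hosts, ids)
    w0 <- BiocGenerics::start(w)[hi] - 1L
    w1 <- BiocGenerics::end(w)[hi]
    summit <- round(stats::runif(nSites, w0 + margin, w1 - margin - 1))
    sChrom <- as.character(GenomicRanges::seqnames(w))[hi]
    chroms <- names(layout)
    pos <- integer(0); str <- character(0); chr <- character(0)
    for (k in seq_len(nSites)) {
      nF <- floor(readsPerSite / 2)
      nR <- readsPerSite - nF
      pF <- round(stats::rnorm(nF, summit[k] - shift, posSd))
      pR <- round(stats::rnorm(nR, summit[k] + shift, posSd))
      pos <- c(pos, pF, pR)
      str <- c(str, rep("+", nF), rep("-", nR))
      chr <- c(chr, rep(sChrom[k], readsPerSite))
    }
    for (ch in chroms) {
      L <- layout[[ch]]
      nBg <- round(backgroundPerKb * L / 1000)
      if (nBg > 0) {
        pos <- c(pos, round(stats::runif(nBg, 0, L - 1)))
        str <- c(str, sample(c("+", "-"), nBg, replace = TRUE))
        chr <- c(chr, rep(ch, nBg))
      }
    }
    pos <- pmin(pmax(pos, readLength - 1), layout[chr] - readLength)
    reads <- GenomicRanges::GRanges(
      chr, IRanges::IRanges(start = pos + 1, width = 1L), strand = str,
      name = sprintf("read%06d", seq_along(pos)))
    summitGr <- GenomicRanges::GRanges(
      sChrom, IRanges::IRanges(start = summit + 1, width = 1L))
    boundIds <- ids[GenomicRanges::countOverlaps(w, summitGr,
                                                 ignore.strand = TRUE) >= 1L]
    list(reads = reads, boundIds = boundIds, hostIds = hosts,
         summits = stats::setNames(summit, hosts),
         summitChrom = stats::setNames(sChrom, hosts))
  })
}

#' Simulate a multi-tissue expression matrix with planted restriction
#'
#' Restricted transcripts (sampled from the non-coding set) are expressed
#' at `onLevel` in the target tissue and `offLevel` elsewhere; all other
#' transcripts get a per-transcript uniform level across every tissue.
#' Each cell is multiplied by log-normal noise with s.d. `noiseSd`
#' (`noiseSd = 0` gives the noiseless matrix, from which the restriction
#' filter recovers the planted set exactly).
#'
#' @param transcripts a [TranscriptSet-class].
#' @param nTissues number of tissues (>= 2, default 8).
#' @param restrictedFrac fraction of transcripts planted as restricted
#'   (default 0.05).
#' @param onLevel,offLevel expression in the target/other tissues
#'   (defaults 10 and 0.1).
#' @param noiseSd multiplicative log-normal noise s.d. (default 0.25).
#' @param targetTissue name of the ON tissue (default `"muscle"`).
#' @param seed RNG seed.
#' @return list with `tissueRpkm` (matrix), `restrictedIds`,
#'   `targetTissue`.
#' @export
simulateTissueMatrix <- function(transcripts, nTissues = 8L,
                                 restrictedFrac = 0.05, onLevel = 10,
                                 offLevel = 0.1, noiseSd = 0.25,
                                 targetTissue = "muscle", seed) {
  if (nTissues < 2L) .stopf("need at least 2 tissues")
  ids <- txId(transcripts)
  nc <- ids[!isCoding(transcripts)]
  nRes <- round(restrictedFrac * length(ids))
  if (nRes > length(nc))
    .stopf("restrictedFrac asks for %d transcripts but only %d are non-coding",
           nRes, length(nc))
  pool <- c("brain", "heart", "liver", "kidney", "lung", "spleen", "testis",
            "thymus", "skin", "gut")
  tissues <- c(targetTissue, pool[seq_len(nTissues - 1L)])
  withSeed(seed, {
    restricted <- sort(sample(nc, nRes))
    m <- matrix(stats::rlnorm(length(ids), log(5), 0.5), length(ids),
                nTissues, dimnames = list(ids, tissues))
    m[match(restricted, ids), ] <- offLevel
    m[match(restricted, ids), targetTissue] <- onLevel
    if (noiseSd > 0)
      m <- m * matrix(stats::rlnorm(length(m), 0, noiseSd), nrow(m))
    list(tissueRpkm = m, restrictedIds = restricted,
         targetTissue = targetTissue)
  })
}

#' Compute precision/recall/F1 of candidate calls against planted truth
#'
#' The truth set is `deIds` intersected with `boundIds`, further
#' intersected with `restrictedIds` when restriction was simulated *and*
#' the report applied a tissue filter (non-`NA` `tissue_restricted`).
#' With no calls there are no false positives, so precision is defined as
#' 1.0 (covering the empty-truth 0/0 corner); recall is 1.0 for empty
#' truth and 0 when truth is non-empty but nothing was called.
#'
#' @param calls a candidate report data.frame ([candidateReport()]).
#' @param truth a [SimTruth-class].
#' @return named numeric vector `precision`, `recall`, `f1`, plus counts
#'   `tp`, `n_called`, `n_truth`.
#' @export
evaluateRecovery <- function(calls, truth) {
  called <- calls$transcript_id[calls$candidate %in% TRUE]
  truthSet <- intersect(truth@deIds, truth@boundIds)
  if (length(truth@restrictedIds) &&
      !all(is.na(calls$tissue_restricted)))
    truthSet <- intersect(truthSet, truth@restrictedIds)
  tp <- length(intersect(called, truthSet))
  precision <- if (length(called) == 0L) 1.0 else tp / length(called)
  recall <- if (length(truthSet) == 0L) 1.0 else tp / length(truthSet)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1, tp = tp,
    n_called = length(called), n_truth = length(truthSet))
}

#' Write / read a SimTruth as JSON
#'
#' @param truth a [SimTruth-class].
#' @param path truth.json path.
#' @export
writeSimTruth <- function(truth, path) {
  obj <- list(seed = truth@seed, params = truth@params,
              de_ids = truth@deIds,
              de_direction = as.list(truth@deDirection),
              bound_ids = truth@boundIds, host_ids = truth@hostIds,
              summits = as.list(truth@summits),
              summit_chrom = as.list(truth@summitChrom),
              restricted_ids = truth@restrictedIds,
              target_tissue = truth@targetTissue)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("SimTruth",
    seed = as.integer(obj$seed), params = as.list(obj$params),
    deIds = as.character(obj$de_ids),
    deDirection = unlist(lapply(obj$de_direction, as.character)),
    boundIds = as.character(obj$bound_ids),
    hostIds = as.character(obj$host_ids),
    summits = unlist(lapply(obj$summits, as.numeric)),
    summitChrom = unlist(lapply(obj$summit_chrom, as.character)),
    restrictedIds = as.character(obj$restricted_ids),
    targetTissue = as.character(obj$target_tissue))
}
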
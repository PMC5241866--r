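#' @include simulate.R
NULL

.configDefaults <- list(
  annotation = NULL, dialect = "bed12", chrom_sizes = NULL, counts = NULL,
  chip_reads = NULL, chip_peaks = NULL, tissue_matrix = NULL,
  out_dir = ".",
  upstream = 5000, downstream = 500, strand_aware = TRUE,
  resolution = 25, flank = 100,
  min_summed_rpkm = 1.0, fold_threshold = 2.0, de_test = "none",
  cond_a = NULL, cond_b = NULL,
  p_cutoff = 0.05, min_run_bins = 2, peak_correction = "bonferroni",
  dedup = FALSE,
  target_tissue = NULL, min_on = 1.0, min_fold_over_others = 5.0,
  seed = 1L)

#' Pipeline run configuration
#'
#' Builds a validated configuration for [runDiscover()] and friends.
#' Unknown keys are rejected; every numeric default equals the method's
#' standard value (window 5000/500 bp, profile 25 bp grid and 100 bp
#' flank, summed-RPKM gate 1, fold threshold 2, peak significance 0.05).
#' `readRunConfig()` loads the same keys from a YAML file, with `...`
#' overrides applied on top.
#'
#' @param ... configuration keys (see `lncScout:::.configDefaults` for the
#'   full set): input paths (`annotation`, `chrom_sizes`, `counts`,
#'   `chip_reads`, `chip_peaks`, `tissue_matrix`), `out_dir`, and the
#'   numeric parameters of every stage.
#' @return a validated `RunConfig` (named list, class `"RunConfig"`).
#' @export
runConfig <- function(...) {
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(!nzchar(names(user)))))
    .stopf("all configuration entries must be named")
  unknown <- setdiff(names(user), names(.configDefaults))
  if (length(unknown))
    .stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.configDefaults, user, keep.null = TRUE)
  with(cfg, {
    if (upstream < 0 || downstream < 0 || (upstream == 0 && downstream == 0))
      .stopf("upstream/downstream out of range")
    if (resolution < 1 || flank < 0) .stopf("resolution/flank out of range")
    if (fold_threshold < 1) .stopf("fold_threshold must be >= 1")
    if (p_cutoff <= 0 || p_cutoff > 1) .stopf("p_cutoff must be in (0, 1]")
    if (min_run_bins < 1) .stopf("min_run_bins must be >= 1")
    if (!de_test %in% c("none", "binomial")) .stopf("invalid de_test")
    if (!peak_correction %in% c("bonferroni", "none"))
      .stopf("invalid peak_correction")
  })
  structure(cfg, class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML configuration file.
#' @export
readRunConfig <- function(path, ...) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) .stopf("%s: expected a YAML mapping", path)
  do.call(runConfig, utils::modifyList(cfg, list(...), keep.null = TRUE))
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:\n")
  for (k in names(x))
    cat(sprintf("  %s: %s\n", k,
                if (is.null(x[[k]])) "~" else paste(x[[k]], collapse = ", ")))
  invisible(x)
}

.configEcho <- function(config) {
  lapply(unclass(config), function(v) if (is.null(v)) NA else v)
}

#' In-memory candidate discovery
#'
#' The full discovery pipeline on in-memory objects, in the fixed stage
#' order: non-coding filter, RPKM, expression gate, differential
#' expression, promoter-window TF classification, optional tissue
#' restriction, ranked candidate report. When `peaks` is `NULL`, reads are
#' profiled with [bindingProfile()] and peaks come from [naivePeakCall()]
#' (logged prominently — the naive caller is plumbing, not a dedicated
#' peak caller).
#'
#' @param transcripts full [TranscriptSet-class] (coding + non-coding).
#' @param em an [ExpressionMatrix-class] covering the transcripts.
#' @param layout named chromosome lengths.
#' @param peaks optional peak `GRanges`; used as-is when supplied.
#' @param reads optional read anchors; profiled when `peaks` is `NULL`.
#' @param tissueRpkm optional tissue matrix for the restriction filter.
#' @param config a [runConfig()] object.
#' @return list with `report`, `summary` (stage counts + config echo),
#'   `profiles` (when computed), `peaks`.
#' @export
discoverCandidates <- function(transcripts, em, layout, peaks = NULL,
                               reads = NULL, tissueRpkm = NULL,
                               config = runConfig()) {
  profiles <- NULL
  if (is.null(peaks)) {
    if (is.null(reads))
      .stopf("either peaks or reads must be supplied")
    if (isTRUE(config$dedup)) reads <- dedupReads(reads)
    message("no peak input supplied: profiling reads and calling peaks with ",
            "the NAIVE Poisson caller (plumbing fallback, not a dedicated ",
            "peak caller)")
    profiles <- bindingProfile(reads, layout,
                               resolution = config$resolution,
                               flank = config$flank)
    peaks <- naivePeakCall(profiles, pCutoff = config$p_cutoff,
                           minRunBins = config$min_run_bins,
                           correction = config$peak_correction)
  } else {
    message("using ", length(peaks), " supplied peak(s); profile stage skipped")
  }
  nc <- filterNoncoding(transcripts)
  if (length(nc) == 0L) .stopf("no non-coding transcripts in the annotation")
  r <- rpkm(em)
  gateIds <- intersect(expressedGate(r, config$min_summed_rpkm), txId(nc))
  samples <- colnames(em)
  condB <- if (is.null(config$cond_a))
    samples[seq_len(floor(length(samples) / 2))] else config$cond_b
  condA <- if (is.null(config$cond_a))
    samples[(floor(length(samples) / 2) + 1L):length(samples)] else
      config$cond_a
  ## DE is called on gated transcripts (stage order: gate -> DE -> bound)
  de <- deCall(em[rownames(em) %in% gateIds, ], condA, condB,
               foldThreshold = config$fold_threshold, test = config$de_test)
  bound <- classifyTfRegulated(nc, peaks, layout,
                               upstream = config$upstream,
                               downstream = config$downstream,
                               strandAware = isTRUE(config$strand_aware))
  restriction <- NULL
  if (!is.null(tissueRpkm)) {
    if (is.null(config$target_tissue))
      .stopf("tissue matrix supplied but target_tissue is not configured")
    restriction <- tissueRestriction(tissueRpkm, config$target_tissue,
                                     minOn = config$min_on,
                                     minFoldOverOthers =
                                       config$min_fold_over_others)
  }
  report <- candidateReport(nc, gateIds, de, bound, layout,
                            restriction = restriction,
                            upstream = config$upstream,
                            downstream = config$downstream,
                            strandAware = isTRUE(config$strand_aware))
  summary <- list(
    n_input = length(transcripts),
    n_noncoding = length(nc),
    n_expressed = length(gateIds),
    n_de = sum(de$direction != "none"),
    n_bound = sum(bound$tf_bound),
    n_candidates = sum(report$candidate),
    n_peaks = length(peaks),
    peak_source = if (length(peaks))
      unique(S4Vectors::mcols(peaks)$source) else character(0),
    config = .configEcho(config))
  list(report = report, summary = summary, profiles = profiles,
       peaks = peaks)
}

#' Run the discovery pipeline from configured files
#'
#' Reads the configured annotation, chromosome sizes, counts, and either
#' peaks or ChIP reads (reads trigger the profile + naive-caller path and
#' write a `profile.bedGraph`), runs [discoverCandidates()], and writes
#' `report.tsv` and `summary.json` into `out_dir`. Identical inputs and
#' configuration produce byte-identical outputs.
#'
#' @param config a [runConfig()] / [readRunConfig()] object.
#' @return (invisibly) the [discoverCandidates()] result plus output paths.
#' @export
runDiscover <- function(config) {
  for (key in c("annotation", "chrom_sizes", "counts"))
    if (is.null(config[[key]]))
      .stopf("configuration is missing required input '%s'", key)
  if (is.null(config$chip_reads) && is.null(config$chip_peaks))
    .stopf("either chip_reads or chip_peaks must be configured")
  transcripts <- readAnnotation(config$annotation, dialect = config$dialect)
  layout <- readChromSizes(config$chrom_sizes)
  em <- readCounts(config$counts, transcripts)
  peaks <- if (!is.null(config$chip_peaks)) readPeaks(config$chip_peaks)
  reads <- if (is.null(peaks)) readChipBed(config$chip_reads)
  tissue <- if (!is.null(config$tissue_matrix))
    readTsvMatrix(config$tissue_matrix)
  res <- discoverCandidates(transcripts, em, layout, peaks = peaks,
                            reads = reads, tissueRpkm = tissue,
                            config = config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(report = file.path(config$out_dir, "report.tsv"),
                summary = file.path(config$out_dir, "summary.json"))
  writeCandidateReport(res$report, paths$report)
  jsonlite::write_json(res$summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(res$profiles)) {
    paths$bedgraph <- file.path(config$out_dir, "profile.bedGraph")
    writeBedGraph(res$profiles, paths$bedgraph)
    paths$peaks <- file.path(config$out_dir, "naive_peaks.bed")
    writePeaks(res$peaks, paths$peaks)
  }
  invisible(c(res, list(paths = paths)))
}

#' Simulate a complete dataset and write it to disk
#'
#' Generates genome + annotation, time-course counts, ChIP reads and a
#' tissue matrix with one shared truth record, writing the same formats
#' the pipeline reads: `annotation.bed12`, `chrom.sizes`, `counts.tsv`,
#' `chip_reads.bed`, `tissue.tsv` and `truth.json`.
#'
#' @param outDir output directory (created).
#' @param seed RNG seed; stage seeds are derived deterministically.
#' @param nChroms,chromLen,nTranscripts,fracNoncoding genome parameters
#'   (see [simulateGenome()]).
#' @param nTimepoints,depth,nbDispersion,deFrac,fold expression parameters
#'   (see [simulateExpression()]).
#' @param boundFrac,readsPerSite,shift,posSd,backgroundPerKb ChIP
#'   parameters (see [simulateChip()]).
#' @param nTissues,restrictedFrac tissue parameters (see
#'   [simulateTissueMatrix()]); `nTissues = 0` skips the tissue matrix.
#' @return (invisibly) list of objects and file paths.
#' @export
runSimulate <- function(outDir, seed, nChroms = 2L, chromLen = 1e6,
                        nTranscripts = 200L, fracNoncoding = 0.5,
                        nTimepoints = 4L, depth = 1e6, nbDispersion = 0.1,
                        deFrac = 0.15, fold = 4.0,
                        boundFrac = 0.1, readsPerSite = 60L, shift = 75L,
                        posSd = 15, backgroundPerKb = 1.0,
                        nTissues = 8L, restrictedFrac = 0.05) {
  sim <- simulateDataset(seed = seed, nChroms = nChroms, chromLen = chromLen,
                         nTranscripts = nTranscripts,
                         fracNoncoding = fracNoncoding,
                         nTimepoints = nTimepoints, depth = depth,
                         nbDispersion = nbDispersion, deFrac = deFrac,
                         fold = fold, boundFrac = boundFrac,
                         readsPerSite = readsPerSite, shift = shift,
                         posSd = posSd, backgroundPerKb = backgroundPerKb,
                         nTissues = nTissues,
                         restrictedFrac = restrictedFrac)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(annotation = file.path(outDir, "annotation.bed12"),
                chrom_sizes = file.path(outDir, "chrom.sizes"),
                counts = file.path(outDir, "counts.tsv"),
                chip_reads = file.path(outDir, "chip_reads.bed"),
                truth = file.path(outDir, "truth.json"))
  writeAnnotation(sim$transcripts, paths$annotation)
  writeChromSizes(sim$layout, paths$chrom_sizes)
  writeCounts(sim$expression, paths$counts)
  writeChipBed(sim$reads, paths$chip_reads)
  if (!is.null(sim$tissueRpkm)) {
    paths$tissue_matrix <- file.path(outDir, "tissue.tsv")
    writeTsvMatrix(sim$tissueRpkm, paths$tissue_matrix, floats = TRUE)
  }
  writeSimTruth(sim$truth, paths$truth)
  invisible(c(sim, list(paths = paths)))
}

#' Simulate a complete dataset in memory
#'
#' @inheritParams runSimulate
#' @return list with `transcripts`, `layout`, `expression`, `reads`,
#'   `tissueRpkm` (or `NULL`) and the combined `truth` ([SimTruth-class]).
#' @export
simulateDataset <- function(seed, nChroms = 2L, chromLen = 1e6,
                            nTranscripts = 200L, fracNoncoding = 0.5,
                            nTimepoints = 4L, depth = 1e6,
                            nbDispersion = 0.1, deFrac = 0.15, fold = 4.0,
                            boundFrac = 0.1, readsPerSite = 60L,
                            shift = 75L, posSd = 15, backgroundPerKb = 1.0,
                            nTissues = 8L, restrictedFrac = 0.05) {
  seed <- as.integer(seed)
  gen <- simulateGenome(nChroms = nChroms, chromLen = chromLen,
                        nTranscripts = nTranscripts,
                        fracNoncoding = fracNoncoding, seed = seed)
  expr <- simulateExpression(gen$transcripts, nTimepoints = nTimepoints,
                             depth = depth, nbDispersion = nbDispersion,
                             deFrac = deFrac, fold = fold,
                             seed = seed + 1000L)
  chip <- simulateChip(gen$transcripts, gen$layout, boundFrac = boundFrac,
                       readsPerSite = readsPerSite, shift = shift,
                       posSd = posSd, backgroundPerKb = backgroundPerKb,
                       seed = seed + 2000L)
  tissue <- if (nTissues >= 2L)
    simulateTissueMatrix(gen$transcripts, nTissues = nTissues,
                         restrictedFrac = restrictedFrac,
                         seed = seed + 3000L)
  truth <- gen$truth
  truth@deIds <- expr$deIds
  truth@deDirection <- expr$deDirection
  truth@boundIds <- chip$boundIds
  truth@hostIds <- chip$hostIds
  truth@summits <- chip$summits
  truth@summitChrom <- chip$summitChrom
  if (!is.null(tissue)) {
    truth@restrictedIds <- tissue$restrictedIds
    truth@targetTissue <- tissue$targetTissue
  }
  truth@params <- c(truth@params,
                    list(nTimepoints = nTimepoints, depth = depth,
                         nbDispersion = nbDispersion, deFrac = deFrac,
                         fold = fold, boundFrac = boundFrac,
                         readsPerSite = readsPerSite, shift = shift,
                         posSd = posSd, backgroundPerKb = backgroundPerKb,
                         nTissues = nTissues,
                         restrictedFrac = restrictedFrac))
  list(transcripts = gen$transcripts, layout = gen$layout,
       expression = expr$expression, reads = chip$reads,
       tissueRpkm = if (is.null(tissue)) NULL else tissue$tissueRpkm,
       truth = truth)
}

#' Profile reads and write a bedGraph track
#'
#' @param readsPath BED6 reads file.
#' @param chromSizesPath chrom.sizes file.
#' @param outPath bedGraph output.
#' @param resolution,flank profile parameters (defaults 25 / 100).
#' @param mergeRuns,trackLine see [writeBedGraph()].
#' @export
runProfile <- function(readsPath, chromSizesPath, outPath,
                       resolution = 25L, flank = 100L, mergeRuns = FALSE,
                       trackLine = FALSE) {
  profiles <- bindingProfile(readChipBed(readsPath),
                             readChromSizes(chromSizesPath),
                             resolution = resolution, flank = flank)
  writeBedGraph(profiles, outPath, mergeRuns = mergeRuns,
                trackLine = trackLine)
  invisible(profiles)
}

#' Score a written report against a written truth record
#'
#' @param reportPath report TSV from [runDiscover()].
#' @param truthPath truth.json from [runSimulate()].
#' @param outPath optional metrics JSON output.
#' @return the [evaluateRecovery()] metrics.
#' @export
runEvaluate <- function(reportPath, truthPath, outPath = NULL) {
  metrics <- evaluateRecovery(readCandidateReport(reportPath),
                              readSimTruth(truthPath))
  if (!is.null(outPath))
    jsonlite::write_json(as.list(metrics), outPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  metrics
}

#' Planted-truth recovery benchmark
#'
#' Runs simulate + discover + evaluate over `nSeeds` independent datasets
#' under the default strong-signal simulation (or any override) and
#' returns per-seed precision/recall/F1 with their means. The expression
#' and binding evidence go through the full pipeline including the
#' profile + naive-caller path. With `tissues = FALSE` (default) the
#' tissue stage is dropped and the truth set is the planted DE-and-bound
#' transcripts — the benchmark that isolates how well the expression and
#' binding evidence recover planted signal with usefully sized truth
#' sets. With `tissues = TRUE` the complete pipeline runs — tissue matrix
#' simulated and the restriction filter applied — and the truth shrinks
#' to DE-and-bound-and-restricted (often empty at the default planting
#' rates, so per-seed metrics are dominated by single calls).
#'
#' @param nSeeds number of independent datasets (default 20).
#' @param baseSeed first seed; seeds are `baseSeed + 0:(nSeeds-1)`.
#' @param config a [runConfig()] for the discovery side.
#' @param tissues include the tissue-restriction stage (default `FALSE`).
#' @param ... simulation overrides passed to [simulateDataset()].
#' @return data.frame of per-seed metrics with a `means` attribute.
#' @export
recoveryBenchmark <- function(nSeeds = 20L, baseSeed = 1L,
                              config = runConfig(), tissues = FALSE, ...) {
  rows <- lapply(seq_len(nSeeds), function(i) {
    sim <- if (tissues) simulateDataset(seed = baseSeed + i - 1L, ...)
      else simulateDataset(seed = baseSeed + i - 1L, nTissues = 0L, ...)
    cfg <- config
    if (tissues && is.null(cfg$target_tissue))
      cfg$target_tissue <- sim$truth@targetTissue
    res <- suppressMessages(
      discoverCandidates(sim$transcripts, sim$expression, sim$layout,
                         reads = sim$reads, tissueRpkm = sim$tissueRpkm,
                         config = cfg))
    c(seed = baseSeed + i - 1L, evaluateRecovery(res$report, sim$truth))
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "means") <- c(precision = mean(out$precision),
                          recall = mean(out$recall), f1 = mean(out$f1))
  out
}
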
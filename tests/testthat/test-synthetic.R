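test_that("genome simulation is deterministic and respects its own contracts", {
  g1 <- simulateGenome(seed = 1)
  g2 <- simulateGenome(seed = 1)
  expect_length(g1$transcripts, 200L)
  expect_identical(txId(g1$transcripts), txId(g2$transcripts))
  expect_equal(BiocGenerics::start(txRanges(g1$transcripts)),
               BiocGenerics::start(txRanges(g2$transcripts)))
  # noncoding fraction is binomial around 0.5
  nNc <- sum(!isCoding(g1$transcripts))
  expect_gt(nNc, 70); expect_lt(nNc, 130)
  expect_true(all(startsWith(txId(g1$transcripts)[!isCoding(g1$transcripts)],
                             "NR_")))
  # no transcript within 6 kb of a chromosome end: windows never clip
  w <- promoterWindows(g1$transcripts, g1$layout)
  expect_true(all(IRanges::width(w) == 5500L))
  expect_error(simulateGenome(nTranscripts = 5000, seed = 1),
               "increase chromLen")
  g3 <- simulateGenome(seed = 2)
  expect_false(identical(BiocGenerics::start(txRanges(g1$transcripts)),
                         BiocGenerics::start(txRanges(g3$transcripts))))
})

test_that("expression simulation plants recoverable fold changes", {
  g <- simulateGenome(seed = 5)
  # deFrac = 0: nothing passes the twofold rule on (near-)noiseless counts
  e0 <- simulateExpression(g$transcripts, deFrac = 0, nbDispersion = 0,
                           seed = 5)
  de <- deCall(e0$expression, c("t5d", "t7d"), c("t0h", "t60h"))
  expect_length(e0$deIds, 0L)
  expect_true(all(de$direction == "none"))
  # near-zero dispersion: every planted |log2FC| lands close to 2
  recovered <- unlist(lapply(1:3, function(s) {
    e <- simulateExpression(g$transcripts, nbDispersion = 0, seed = s)
    d <- deCall(e$expression, c("t5d", "t7d"), c("t0h", "t60h"))
    d$log2_fc[match(e$deIds, d$transcript_id)] *
      ifelse(e$deDirection[e$deIds] == "up", 1, -1)
  }))
  # realized fold changes sit near 2 up to Poisson noise on the lowest
  # expressed transcripts and the +/-0.2 compositional shift of RPKM
  expect_gt(min(recovered), 1.2)
  expect_lt(max(recovered), 2.8)
  expect_equal(mean(recovered), 2, tolerance = 0.05)
  # determinism
  eA <- simulateExpression(g$transcripts, seed = 11)
  eB <- simulateExpression(g$transcripts, seed = 11)
  expect_identical(SummarizedExperiment::assay(eA$expression, "counts"),
                   SummarizedExperiment::assay(eB$expression, "counts"))
  expect_identical(eA$deIds, eB$deIds)
})

test_that("planted summits always lie inside their host promoter window", {
  for (s in 1:5) {
    sim <- simulateDataset(seed = s, nTissues = 0)
    w <- promoterWindows(sim$transcripts, sim$layout)
    hosts <- sim$truth@hostIds
    hw <- w[match(hosts, txId(sim$transcripts))]
    inside <- sim$truth@summits >= BiocGenerics::start(hw) - 1 &
      sim$truth@summits < BiocGenerics::end(hw)
    expect_true(all(inside))
    expect_true(all(hosts %in% sim$truth@boundIds))
    expect_true(all(sim$truth@deIds %in% txId(sim$transcripts)))
  }
})

test_that("a noiseless single site produces its maximum plateau between the strand clusters", {
  g <- simulateGenome(seed = 3)
  chip <- simulateChip(g$transcripts, g$layout, boundFrac = 1 / 200,
                       posSd = 0, backgroundPerKb = 0, seed = 3)
  expect_length(chip$hostIds, 1L)
  summit <- unname(chip$summits)
  prof <- bindingProfile(chip$reads, g$layout)[[chip$summitChrom[[1]]]]
  grid <- gridPositions(prof)
  v <- profileCounts(prof)
  plateau <- grid >= summit - 25 & grid <= summit + 25
  expect_true(all(v[plateau] == 60L))
  expect_true(all(v[!plateau] < 60L))
  expect_true(all(v[grid < summit - 75 - 100 | grid > summit + 75 + 100] == 0L))
})

test_that("pure background yields no naive peak calls in nearly all datasets", {
  clean <- 0L
  for (s in 1:10) {
    g <- simulateGenome(seed = s)
    chip <- simulateChip(g$transcripts, g$layout, boundFrac = 0, seed = s)
    pk <- naivePeakCall(bindingProfile(chip$reads, g$layout))
    if (length(pk) == 0L) clean <- clean + 1L
  }
  expect_gte(clean, 9L)
})

test_that("ChIP simulation is deterministic and writes identical BED", {
  g <- simulateGenome(seed = 8)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeChipBed(simulateChip(g$transcripts, g$layout, seed = 4)$reads, p1)
  writeChipBed(simulateChip(g$transcripts, g$layout, seed = 4)$reads, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("noiseless tissue matrices recover exactly the planted restricted set", {
  g <- simulateGenome(seed = 6)
  tm <- simulateTissueMatrix(g$transcripts, noiseSd = 0, seed = 6)
  called <- tissueRestriction(tm$tissueRpkm, tm$targetTissue)
  expect_setequal(names(called)[called], tm$restrictedIds)
  none <- simulateTissueMatrix(g$transcripts, restrictedFrac = 0,
                               noiseSd = 0, seed = 6)
  expect_length(none$restrictedIds, 0L)
  calledNone <- tissueRestriction(none$tissueRpkm, none$targetTissue)
  expect_false(any(calledNone))
  # default (noisy) matrices still recover the planted set
  tmN <- simulateTissueMatrix(g$transcripts, seed = 7)
  calledN <- tissueRestriction(tmN$tissueRpkm, tmN$targetTissue)
  expect_setequal(names(calledN)[calledN], tmN$restrictedIds)
})

test_that("recovery metrics implement the stated precision/recall conventions", {
  truth <- methods::new("SimTruth", seed = 1L, params = list(),
                        deIds = c("a", "b", "c"), deDirection = character(0),
                        boundIds = c("a", "b", "c", "x"),
                        hostIds = character(0), summits = numeric(0),
                        summitChrom = character(0),
                        restrictedIds = character(0),
                        targetTissue = character(0))
  calls <- data.frame(transcript_id = c("a", "b", "x", "z"),
                      candidate = c(TRUE, TRUE, TRUE, FALSE),
                      tissue_restricted = NA)
  m <- evaluateRecovery(calls, truth)
  expect_equal(unname(m[c("precision", "recall", "f1")]), rep(2 / 3, 3))
  # perfect calls
  calls2 <- data.frame(transcript_id = c("a", "b", "c"), candidate = TRUE,
                       tissue_restricted = NA)
  expect_equal(unname(evaluateRecovery(calls2, truth)[1:3]), c(1, 1, 1))
  # no calls: no false positives (precision 1), recall 0 against real truth
  calls3 <- data.frame(transcript_id = "a", candidate = FALSE,
                       tissue_restricted = NA)
  m3 <- evaluateRecovery(calls3, truth)
  expect_equal(unname(m3["precision"]), 1)
  expect_equal(unname(m3["recall"]), 0)
  # restriction shrinks the truth only when the report used the filter
  truth@restrictedIds <- "a"
  mNoFilter <- evaluateRecovery(calls, truth)
  expect_equal(unname(mNoFilter["n_truth"]), 3)
  calls$tissue_restricted <- c(TRUE, FALSE, FALSE, FALSE)
  mFilter <- evaluateRecovery(calls, truth)
  expect_equal(unname(mFilter["n_truth"]), 1)
})

test_that("truth records survive a JSON round-trip", {
  sim <- simulateDataset(seed = 12)
  path <- withr::local_tempfile()
  writeSimTruth(sim$truth, path)
  back <- readSimTruth(path)
  expect_identical(back@deIds, sim$truth@deIds)
  expect_identical(back@boundIds, sim$truth@boundIds)
  expect_equal(back@summits, sim$truth@summits)
  expect_identical(back@restrictedIds, sim$truth@restrictedIds)
})
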
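test_that("BED6 reads reduce to strand-aware 5' anchors", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t100\t136\tr1\t0\t+",
               "chr1\t100\t136\tr2\t0\t-"), path)
  reads <- readChipBed(path)
  expect_equal(BiocGenerics::start(reads) - 1L, c(100L, 135L))
  expect_identical(as.character(GenomicRanges::strand(reads)), c("+", "-"))
  writeLines("chr1\t100\t136\tr1\t0\t.", path)
  expect_error(readChipBed(path), "line 1.*strand")
  writeLines("chr1\t100\t136", path)
  expect_error(readChipBed(path), "BED6")
})

test_that("read anchors survive a BED round-trip and dedup collapses triples", {
  reads <- mkReads("chr1", c(500, 500, 620), c("+", "+", "-"))
  path <- withr::local_tempfile()
  writeChipBed(reads, path)
  back <- readChipBed(path)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(reads))
  expect_identical(as.character(GenomicRanges::strand(back)),
                   as.character(GenomicRanges::strand(reads)))
  expect_length(dedupReads(reads), 2L)
})

test_that("single-read profiles match the oriented-counting definition", {
  layout <- c(chr1 = 1000)
  grid <- seq(0, 975, by = 25)
  # a forward read points downstream: it covers grid 200..300 only
  prof <- bindingProfile(mkReads("chr1", 200, "+"), layout)$chr1
  expect_equal(profileCounts(prof)[match(c(200, 225, 250, 275, 300), grid)],
               rep(1L, 5))
  expect_true(all(profileCounts(prof)[grid < 200 | grid > 300] == 0L))
  # a reverse read points upstream: grid 100..200
  prof <- bindingProfile(mkReads("chr1", 200, "-"), layout)$chr1
  expect_equal(which(profileCounts(prof) == 1L), match(seq(100, 200, 25), grid))
  # inward-facing pair: plateau of 2 between the reads
  prof <- bindingProfile(mkReads("chr1", c(150, 250), c("+", "-")), layout)$chr1
  expect_true(all(profileCounts(prof)[grid >= 150 & grid <= 250] == 2L))
  expect_true(all(profileCounts(prof)[grid < 150 | grid > 250] <= 1L))
})

test_that("profiles equal the brute-force oracle on random instances", {
  set.seed(23)
  layout <- c(chrA = 5000, chrB = 3000)
  for (rep in 1:5) {
    nA <- 80; nB <- 40
    pos <- c(sample.int(5000, nA) - 1L, sample.int(3000, nB) - 1L)
    str <- sample(c("+", "-"), nA + nB, replace = TRUE)
    chrom <- rep(c("chrA", "chrB"), c(nA, nB))
    profs <- bindingProfile(mkReads(chrom, pos, str), layout)
    for (ch in names(layout)) {
      onch <- chrom == ch
      expect_equal(as.numeric(profileCounts(profs[[ch]])),
                   bruteProfile(pos[onch], str[onch],
                                gridPositions(profs[[ch]]), 100))
    }
  }
})

test_that("an interior read contributes floor(flank/res)+1 bins when grid-aligned, else one fewer", {
  layout <- c(chr1 = 10000)
  for (p0 in c(5000, 5010, 5024)) for (s in c("+", "-")) {
    prof <- bindingProfile(mkReads("chr1", p0, s), layout)$chr1
    expect_equal(sum(profileCounts(prof)), if (p0 %% 25 == 0) 5L else 4L)
  }
})

test_that("reflecting reads reflects the profile onto the mirrored grid", {
  set.seed(29)
  L <- 4000
  pos <- sample.int(L - 400, 60) + 199L
  str <- sample(c("+", "-"), 60, replace = TRUE)
  prof <- bindingProfile(mkReads("chr1", pos, str), c(chr1 = L))$chr1
  mpos <- L - 1 - pos
  mstr <- ifelse(str == "+", "-", "+")
  mirroredAt <- bruteProfile(mpos, mstr, L - 1 - gridPositions(prof), 100)
  expect_equal(as.numeric(profileCounts(prof)), mirroredAt)
})

test_that("bedGraph output omits zero runs and can merge equal neighbours", {
  v <- integer(40); v[9] <- 1L                  # grid position 200
  path <- withr::local_tempfile()
  writeBedGraph(mkProfile(v), path)
  expect_identical(readLines(path), "chr1\t200\t225\t1")
  writeBedGraph(mkProfile(integer(40)), path)
  expect_identical(readLines(path), character(0))
  v2 <- integer(40); v2[9:11] <- 2L; v2[12] <- 1L
  writeBedGraph(mkProfile(v2), path, mergeRuns = TRUE)
  expect_identical(readLines(path),
                   c("chr1\t200\t275\t2", "chr1\t275\t300\t1"))
  writeBedGraph(mkProfile(v2), path, trackLine = TRUE)
  expect_identical(readLines(path)[1], "track type=bedGraph")
})

test_that("peak BED ingestion takes scores from column 5 and validates intervals", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t7000\t7200\ts1\t31", "chr1\t100\t300"), path)
  pk <- readPeaks(path)
  expect_equal(BiocGenerics::start(pk) - 1L, c(7000L, 100L))
  expect_equal(pk$score, c(31, 0))
  expect_identical(unique(pk$source), "external")
  writeLines("chr1\t500\t400\tbad", path)
  expect_error(readPeaks(path), "line 1.*[Ii]nverted")
})

test_that("the naive Poisson caller finds planted runs and respects the run rule", {
  v <- integer(4000); v[100:102] <- 50L        # lambda ~ 0.0375
  pk <- naivePeakCall(mkProfile(v, chromLength = 1e5))
  expect_length(pk, 1L)
  expect_equal(BiocGenerics::start(pk) - 1L, 99 * 25)
  expect_equal(BiocGenerics::end(pk), 102 * 25)
  expect_equal(pk$score, 50)
  expect_identical(unique(pk$source), "naive")
  # uniform profile: every bin equals the mean -> nothing significant
  expect_length(naivePeakCall(mkProfile(rep(20L, 4000),
                                        chromLength = 1e5)), 0L)
  # an isolated significant bin fails min_run_bins = 2
  v1 <- integer(4000); v1[100] <- 50L
  expect_length(naivePeakCall(mkProfile(v1, chromLength = 1e5)), 0L)
  expect_length(naivePeakCall(mkProfile(v1, chromLength = 1e5),
                              minRunBins = 1L), 1L)
  # the uncorrected per-bin rule flags modest counts that the
  # multiple-testing-corrected default rejects
  v2 <- rep(1L, 400); v2[50:51] <- 4L          # lambda ~ 1.015
  expect_length(naivePeakCall(mkProfile(v2, chromLength = 1e4),
                              correction = "none"), 1L)
  expect_length(naivePeakCall(mkProfile(v2, chromLength = 1e4)), 0L)
})

test_that("peak-window overlap uses half-open semantics", {
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 10500))
  keep <- mkPeaks("chr1", 7000, 7200)
  abut <- mkPeaks("chr1", 10500, 10600)
  graze <- mkPeaks("chr1", 4990, 5001)
  expect_length(peaksOverlapping(keep, w), 1L)
  expect_length(peaksOverlapping(abut, w), 0L)
  expect_length(peaksOverlapping(graze, w), 1L)
})
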
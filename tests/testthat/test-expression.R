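mkEm <- function(counts, len, lib) {
  ExpressionMatrix(counts, exonLengths = len, librarySizes = lib)
}

test_that("rpkm matches its closed form and algebraic scaling laws", {
  m <- matrix(c(100, 0, 100, 200), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  em <- mkEm(m, len = c(2000, 1000), lib = c(1e7, 2e7))
  r <- rpkm(em)
  expect_equal(r["a", "s1"], 5.0)        # 100 reads, 2 kb, 10M reads
  expect_equal(r["a", "s2"], 0)
  expect_equal(r["b", "s2"], 200 * 1e9 / (1000 * 2e7))
  # doubling the library size halves RPKM
  em2 <- mkEm(m, len = c(2000, 1000), lib = c(2e7, 2e7))
  expect_equal(rpkm(em2)["a", "s1"], 2.5)
  # randomized: linear in counts, inverse in length and library size
  set.seed(11)
  for (rep in 1:5) {
    cts <- matrix(rpois(12, 500), 3,
                  dimnames = list(letters[1:3], c("x", "y", "z", "w")[1:4]))
    len <- sample(500:5000, 3); lib <- runif(4, 1e6, 1e8)
    r1 <- rpkm(mkEm(cts, len, lib))
    expect_equal(rpkm(mkEm(2 * cts, len, lib)), 2 * r1)
    expect_equal(rpkm(mkEm(cts, 2 * len, lib)), r1 / 2)
    expect_equal(rpkm(mkEm(cts, len, 2 * lib)), r1 / 2)
  }
})

test_that("the expression gate is strict and monotone in added samples", {
  tab <- rbind(a = c(0.2, 0.3, 0.4, 0.2),   # sums to 1.1 -> kept
               b = c(0.25, 0.25, 0.25, 0.25), # sums to exactly 1 -> dropped
               c = c(0, 0, 0, 0))
  expect_identical(expressedGate(tab), "a")
  # adding a sample can never remove a retained transcript
  set.seed(5)
  for (rep in 1:10) {
    t0 <- matrix(runif(30, 0, 0.6), 6)
    rownames(t0) <- paste0("t", 1:6)
    kept0 <- expressedGate(t0)
    t1 <- cbind(t0, runif(6, 0, 2))
    expect_true(all(kept0 %in% expressedGate(t1)))
  }
})

test_that("deCall applies the fold rule with zero/infinity conventions", {
  cts <- matrix(c(8, 8, 2, 2,    # up 4-fold
                  3, 3, 2, 2,    # below twofold
                  0, 0, 10, 10,  # zero vs positive
                  0, 0, 0, 0),   # all zero
                4, byrow = TRUE,
                dimnames = list(c("up4", "mild", "off", "zero"),
                                c("a1", "a2", "b1", "b2")))
  em <- mkEm(cts, len = rep(1000, 4), lib = rep(1e6, 4))
  de <- deCall(em, condA = c("a1", "a2"), condB = c("b1", "b2"))
  expect_equal(de$log2_fc[de$transcript_id == "up4"], 2)
  expect_identical(de$direction[de$transcript_id == "up4"], "up")
  expect_equal(de$log2_fc[de$transcript_id == "mild"], log2(3) - log2(2))
  expect_identical(de$direction[de$transcript_id == "mild"], "none")
  expect_identical(de$log2_fc[de$transcript_id == "off"], -Inf)
  expect_identical(de$direction[de$transcript_id == "off"], "down")
  expect_equal(de$log2_fc[de$transcript_id == "zero"], 0)
  expect_identical(de$direction[de$transcript_id == "zero"], "none")
  # a looser fold threshold promotes the 1.5-fold transcript
  de14 <- deCall(em, c("a1", "a2"), c("b1", "b2"), foldThreshold = 1.4)
  expect_identical(de14$direction[de14$transcript_id == "mild"], "up")
  expect_error(deCall(em, character(0), "b1"), "non-empty")
  expect_error(deCall(em, c("a1", "b1"), c("b1", "b2")), "disjoint")
})

test_that("swapping conditions negates every finite log2_fc exactly", {
  set.seed(21)
  cts <- matrix(rpois(40, 300), 10,
                dimnames = list(sprintf("t%02d", 1:10),
                                c("a1", "a2", "b1", "b2")))
  cts[3, 1:2] <- 0
  em <- mkEm(cts, len = sample(500:3000, 10), lib = runif(4, 5e5, 2e6))
  fwd <- deCall(em, c("a1", "a2"), c("b1", "b2"))
  rev <- deCall(em, c("b1", "b2"), c("a1", "a2"))
  expect_identical(fwd$log2_fc, -rev$log2_fc)
  swap <- c(up = "down", down = "up", none = "none")
  expect_identical(unname(swap[fwd$direction]), rev$direction)
})

test_that("the binomial stand-in matches independent tail summation", {
  cts <- matrix(c(0, 10), 1, dimnames = list("t", c("a", "b")))
  em <- mkEm(cts, len = 1000, lib = c(1e6, 1e6))
  de <- deCall(em, "a", "b", test = "binomial")
  expect_equal(de$p_value, 2 * (1 / 2)^10, tolerance = 1e-12)
  expect_match(attr(de, "test"), "stand-in")
  # independent summation of the exact mass function, assorted cases
  for (case in list(c(0, 10, 0.5), c(3, 17, 0.25), c(40, 100, 0.5),
                    c(7, 7, 0.9), c(250, 600, 0.45))) {
    expect_equal(stats::binom.test(case[1], case[2], case[3])$p.value,
                 bruteBinomTwoSided(case[1], case[2], case[3]),
                 tolerance = 1e-12)
  }
})

test_that("clustering preprocessing yields unit-scale centred rows and drops constants", {
  out <- preprocessForClustering(rbind(a = c(1, 3)))
  expect_equal(unname(out["a", ]), c(-sqrt(0.5), sqrt(0.5)))
  expect_warning(
    out <- preprocessForClustering(rbind(a = c(1, 3, 7), b = c(5, 5, 5))),
    "constant")
  expect_identical(attr(out, "dropped"), "b")
  expect_identical(rownames(out), "a")
  set.seed(31)
  tab <- matrix(rexp(60, 0.2), 10)
  rownames(tab) <- paste0("g", 1:10)
  norm <- preprocessForClustering(tab)
  expect_true(all(abs(rowMeans(norm)) < 1e-9))
  expect_true(all(abs(rowSums(norm^2) - 1) < 1e-9))
})

test_that("tissue restriction requires both the on-level and the fold margin", {
  m <- rbind(good = c(10, 0.5, 0.2), loud = c(10, 5, 1),
             faint = c(0.5, 0.5, 0.5), lonely = c(10, 0, 0))
  colnames(m) <- c("muscle", "brain", "liver")
  r <- tissueRestriction(m, "muscle")
  expect_identical(unname(r), c(TRUE, FALSE, FALSE, TRUE))
  expect_error(tissueRestriction(m, "kidney"), "unknown tissue")
  expect_error(tissueRestriction(m[, 1, drop = FALSE], "muscle"),
               "two tissues")
})

test_that("counts TSV round-trips through an ExpressionMatrix", {
  cts <- matrix(c(5L, 9L, 0L, 14L), 2,
                dimnames = list(c("NR_1", "NM_2"), c("t0h", "t60h")))
  em <- mkEm(cts, len = c(1500, 900), lib = c(2e6, 3e6))
  path <- withr::local_tempfile()
  writeCounts(em, path)
  back <- readCounts(path, transcripts = c(NR_1 = 1500, NM_2 = 900),
                     librarySizes = c(t0h = 2e6, t60h = 3e6))
  expect_equal(SummarizedExperiment::assay(back, "counts"),
               SummarizedExperiment::assay(em, "counts"))
  expect_equal(rpkm(back), rpkm(em))
})
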
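mk_truth <- function(n = 20, seed = 1, chrom = "chr1") {
  set.seed(seed)
  data.frame(chrom = chrom, pos = sort(sample(100:9000, n)),
             ref = sample(c("A", "C", "G", "T"), n, TRUE),
             alt = sample(c("AT", "C", "G", "TTA"), n, TRUE),
             gt = sample(c("0|1", "1|0", "1|1"), n, TRUE),
             stringsAsFactors = FALSE)
}

test_that("a call set matches itself perfectly", {
  truth <- mk_truth(30)
  m <- matchCalls(truth, truth)
  expect_equal(m$overall$sensitivity, 1)
  expect_equal(m$overall$precision, 1)
  expect_equal(m$overall$f1, 1)
  expect_identical(m$overall$genotype_mismatch, 0L)
})

test_that("genotype mismatches are tallied separately from TP", {
  truth <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "C",
                      gt = "0|1")
  call_hom <- transform(truth, gt = "1/1")
  m <- matchCalls(call_hom, truth)
  expect_identical(m$overall$genotype_mismatch, 1L)
  expect_identical(m$overall$tp, 0L)
  expect_identical(m$overall$fp, 1L)
  expect_identical(m$overall$fn, 1L)
  ## allele-order / phase notation never matters
  call_flip <- transform(truth, gt = "1|0")
  expect_identical(matchCalls(call_flip, truth)$overall$tp, 1L)
})

test_that("summary arithmetic follows the standard definitions", {
  set.seed(2)
  truth <- mk_truth(100, seed = 3)
  calls <- truth[1:98, ]                      # 2 FN
  extra <- mk_truth(2, seed = 4, chrom = "chr2")
  calls <- rbind(calls, extra)                # 2 FP
  m <- matchCalls(calls, truth)
  expect_identical(m$overall$tp, 98L)
  expect_identical(m$overall$fp, 2L)
  expect_identical(m$overall$fn, 2L)
  expect_equal(100 * m$overall$sensitivity, 98)
  expect_equal(100 * m$overall$precision, 98)
  expect_equal(100 * m$overall$f1, 98)
})

test_that("matching equals a brute-force all-pairs comparator", {
  set.seed(5)
  for (i in 1:20) {
    truth <- mk_truth(sample(5:50, 1), seed = i)
    calls <- mk_truth(sample(5:50, 1), seed = i + 100)
    ## splice in some true matches and genotype mismatches
    take <- sample(nrow(truth), min(nrow(truth), sample(3:10, 1)))
    calls <- rbind(calls, truth[take, ])
    flip <- sample(nrow(calls), 3)
    calls$gt[flip] <- ifelse(calls$gt[flip] == "1|1", "0|1", "1|1")
    m <- matchCalls(calls, truth)
    ## brute force: for every call scan the whole truth table
    tp <- 0L; gm <- 0L
    gtk <- function(g) paste(sort(strsplit(g, "[/|]")[[1L]]), collapse = "")
    for (ci in seq_len(nrow(calls))) {
      for (ti in seq_len(nrow(truth))) {
        if (calls$chrom[ci] == truth$chrom[ti] &&
            calls$pos[ci] == truth$pos[ti] &&
            calls$ref[ci] == truth$ref[ti] &&
            calls$alt[ci] == truth$alt[ti]) {
          if (gtk(calls$gt[ci]) == gtk(truth$gt[ti])) tp <- tp + 1L
          else gm <- gm + 1L
        }
      }
    }
    expect_identical(m$overall$tp, tp)
    expect_identical(m$overall$genotype_mismatch, gm)
  }
})

test_that("confident regions restrict both call sets", {
  truth <- mk_truth(50, seed = 9)
  bed <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4000))
  m <- matchCalls(truth, truth, confidentBed = bed)
  expect_identical(m$overall$tp + m$overall$fn,
                   sum(truth$pos <= 4000))
})

test_that("phase precision reproduces printed contingency arithmetic", {
  expect_equal(round(phasePrecisionPercent(12726, 315), 1), 97.6)
  expect_equal(round(phasePrecisionPercent(9737, 315), 1), 96.9)
  expect_equal(round(phasePrecisionPercent(13303, 802), 1), 94.3)
  expect_true(is.na(phasePrecisionPercent(0, 0)))
})

test_that("phase comparison agrees with itself and bins partition pairs", {
  set.seed(8)
  n <- 40L
  pos <- sort(sample(100:5000, n))
  truth <- data.frame(chrom = "chr1", pos = pos,
                      ref = sample(c("A", "C"), n, TRUE),
                      alt = sample(c("G", "T"), n, TRUE),
                      gt = sample(c("0|1", "1|0"), n, TRUE),
                      stringsAsFactors = FALSE)
  calls <- truth
  calls$ps <- 1L                      # one big phase set
  calls$qual <- 50
  pp <- phasePrecision(calls, truth)
  expect_true(all(pp$precision == 100))
  expect_identical(sum(pp$correct) + sum(pp$incorrect), n - 1L)
  ## flipping one call's orientation makes its two adjacent pairs incorrect
  calls2 <- calls
  calls2$gt[10L] <- ifelse(calls$gt[10L] == "0|1", "1|0", "0|1")
  pp2 <- phasePrecision(calls2, truth)
  expect_identical(sum(pp2$incorrect), 2L)
  ## quality filtering drops low-quality members before pairing
  calls3 <- calls
  calls3$qual[2L] <- 5
  pp3 <- phasePrecision(calls3, truth)
  expect_identical(sum(pp3$correct) + sum(pp3$incorrect), n - 2L)
})

test_that("pairs without usable truth phase are discarded", {
  truth <- data.frame(chrom = "chr1", pos = c(100L, 110L, 120L),
                      ref = "A", alt = "C",
                      gt = c("0|1", "1/1", "0|1"),
                      stringsAsFactors = FALSE)
  calls <- truth
  calls$gt <- c("0|1", "0|1", "0|1")
  calls$ps <- 100L
  calls$qual <- 99
  pp <- phasePrecision(calls, truth)
  ## the hom-truth middle variant breaks both adjacent pairs
  expect_identical(sum(pp$correct) + sum(pp$incorrect), 0L)
})
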
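test_that("candidate regions require three supporting reads", {
  ref <- mk_ref(400, seed = 6)
  refseq <- ref[["chr1"]]
  span <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 400))
  mut <- function(start, at) {
    s <- substr(refseq, start, start + 49L)
    off <- at - start + 1L
    substr(s, off, off) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, off, off))[1L]
    s
  }
  ## two mismatching reads: below threshold
  rd <- mk_reads(c(80, 90, 85, 95), "50M",
                 c(mut(80, 101), mut(90, 101),
                   substr(refseq, 85, 134), substr(refseq, 95, 144)))
  expect_identical(length(findCandidateRegions(rd, ref, span)), 0L)
  ## three mismatching reads at position 101 -> region padded by 4
  rd <- mk_reads(c(80, 90, 85), "50M",
                 c(mut(80, 101), mut(90, 101), mut(85, 101)))
  cr <- findCandidateRegions(rd, ref, span)
  expect_identical(length(cr), 1L)
  expect_identical(GenomicRanges::start(cr), 97L)
  expect_identical(GenomicRanges::end(cr), 105L)
  expect_identical(S4Vectors::mcols(cr)$seeds, "101")
})

test_that("nearby candidate regions merge", {
  ref <- mk_ref(600, seed = 6)
  refseq <- ref[["chr1"]]
  span <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 600))
  mut <- function(start, at) {
    s <- substr(refseq, start, start + 59L)
    for (a in at) {
      off <- a - start + 1L
      substr(s, off, off) <- setdiff(c("A", "C", "G", "T"),
                                     substr(s, off, off))[1L]
    }
    s
  }
  rd <- mk_reads(rep(c(90, 95, 100), 2), "60M",
                 c(mut(90, c(101, 141)), mut(95, c(101, 141)),
                   mut(100, c(101, 141)),
                   mut(90, 101), mut(95, 141), mut(100, c(101, 141))))
  cr <- findCandidateRegions(rd, ref, span)
  expect_identical(length(cr), 1L)          # seeds 101 and 141 merge (< 100)
  expect_identical(S4Vectors::mcols(cr)$seeds, "101,141")
})

test_that("window planning steps by k from 100 bases upstream", {
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(997, 1005))
  S4Vectors::mcols(reg)$seeds <- "1001"
  w <- planWindows(reg)
  expect_identical(GenomicRanges::start(w), c(901L, 926L, 951L, 976L, 1001L))
  expect_true(all(GenomicRanges::width(w) == 150L))
  ## clamping at the contig start
  S4Vectors::mcols(reg)$seeds <- "50"
  w <- planWindows(reg)
  expect_identical(GenomicRanges::start(w)[1L], 1L)
  ## step size is configurable
  S4Vectors::mcols(reg)$seeds <- "1001"
  w10 <- planWindows(reg, stepSize = 10L)
  expect_identical(diff(GenomicRanges::start(w10))[1L], 10L)
})

test_that("window-call merging follows majority vote with het ties", {
  wc <- function(gt, win) data.frame(chrom = "chr1", pos = 100L, ref = "A",
                                     alt = "C", gt = gt, kmer_prob = 0.9,
                                     pos_in_window = 50L, win_start = win)
  calls <- rbind(wc("het0", 1L), wc("het1", 26L), wc("hom", 51L))
  m <- mergeWindowCalls(calls)
  expect_identical(m$genotype, "het")       # het in 2, hom in 1
  expect_identical(m$window_count, 3L)
  calls <- rbind(wc("hom", 1L), wc("hom", 26L), wc("het0", 51L))
  expect_identical(mergeWindowCalls(calls)$genotype, "hom")
  calls <- rbind(wc("het0", 1L), wc("hom", 26L))
  expect_identical(mergeWindowCalls(calls)$genotype, "het")   # tie -> het
  ## merging a single window's calls returns them unchanged (idempotence)
  single <- wc("het1", 1L)
  m1 <- mergeWindowCalls(single)
  expect_identical(nrow(m1), 1L)
  expect_identical(m1$genotype, "het")
  expect_identical(m1$kmer_min, 0.9)
})

test_that("merging matches an exhaustive vote tally on random cases", {
  set.seed(12)
  for (i in 1:200) {
    nwin <- sample(1:6, 1)
    gts <- sample(c("het0", "het1", "hom"), nwin, replace = TRUE)
    calls <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "T",
                        gt = gts, kmer_prob = runif(nwin),
                        pos_in_window = sample(0:149, nwin, TRUE),
                        win_start = seq_len(nwin))
    m <- mergeWindowCalls(calls)
    expect_identical(m$genotype, oracle_vote(gts))
    expect_identical(m$window_count, nwin)
    expect_equal(m$kmer_min, min(calls$kmer_prob))
    expect_equal(m$kmer_mean, mean(calls$kmer_prob))
  }
})

test_that("cis/trans annotation is symmetric and phase sets are consistent", {
  wc <- function(pos, ref, alt, gt, win)
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt, gt = gt,
               kmer_prob = 0.9, pos_in_window = pos - win,
               win_start = win)
  ## two variants always on the same decoded haplotype -> cis
  calls <- rbind(wc(100L, "A", "C", "het0", 1L), wc(120L, "G", "T", "het0", 1L),
                 wc(100L, "A", "C", "het1", 26L), wc(120L, "G", "T", "het1", 26L))
  ref <- mk_ref(400, seed = 2)
  m <- annotateFeatures(mergeWindowCalls(calls), calls,
                        mk_reads(integer(0), character(0), character(0)),
                        ref)
  expect_identical(m$n_cis, c(1L, 1L))
  expect_identical(m$n_trans, c(0L, 0L))
  expect_identical(m$ps, c(100L, 100L))
  expect_identical(m$gt[1L], m$gt[2L])      # same haplotype orientation
  ## opposite haplotypes -> trans, opposite orientations in the phase set
  calls <- rbind(wc(100L, "A", "C", "het0", 1L), wc(120L, "G", "T", "het1", 1L))
  m <- annotateFeatures(mergeWindowCalls(calls), calls,
                        mk_reads(integer(0), character(0), character(0)),
                        ref)
  expect_identical(m$n_trans, c(1L, 1L))
  expect_true(m$gt[1L] != m$gt[2L])
  expect_identical(m$ps, c(100L, 100L))
})

test_that("pileup features report depth and alt support", {
  ref <- mk_ref(300, seed = 9)
  refseq <- ref[["chr1"]]
  alt <- setdiff(c("A", "C", "G", "T"), substr(refseq, 120, 120))[1L]
  mut <- function(start) {
    s <- substr(refseq, start, start + 59L)
    substr(s, 120 - start + 1L, 120 - start + 1L) <- alt
    s
  }
  rd <- rbind(mk_reads(c(90, 95, 100), "60M",
                       vapply(c(90, 95, 100), mut, character(1))),
              mk_reads(c(92, 97), "60M",
                       substring(refseq, c(92, 97), c(151, 156))))
  calls <- data.frame(chrom = "chr1", pos = 120L, ref = substr(refseq, 120, 120),
                      alt = alt, gt = "het0", kmer_prob = 0.8,
                      pos_in_window = 30L, win_start = 90L)
  m <- annotateFeatures(mergeWindowCalls(calls), calls, rd, ref)
  expect_identical(m$depth, 5L)
  expect_identical(m$alt_support, 3L)
  expect_identical(m$is_indel, 0L)
})
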
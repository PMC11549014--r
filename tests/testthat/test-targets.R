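ref300 <- mk_ref(300, seed = 8)
refseq300 <- ref300[["chr1"]]

test_that("window labels follow the class precedence", {
  w <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(c(1, 1, 1), width = 150))
  snv <- data.frame(chrom = "chr1", pos = 50L, ref = "A", alt = "C",
                    gt = "0|1")
  lab <- labelRegions(mk_window(1), snv)
  expect_identical(lab$label, "snv")
  dels <- data.frame(chrom = "chr1", pos = c(40L, 90L),
                     ref = c("AAT", "CG"), alt = c("A", "C"),
                     gt = c("0|1", "1|1"))
  expect_identical(labelRegions(mk_window(1), dels)$label, "multi_indel")
  expect_identical(
    labelRegions(mk_window(1), snv[0, , drop = FALSE])$label,
    "true_negative")
  ## insertion beats deletion beats snv
  mix <- data.frame(chrom = "chr1", pos = c(40L, 90L), ref = c("A", "A"),
                    alt = c("AGG", "C"), gt = c("0|1", "0|1"))
  expect_identical(labelRegions(mk_window(1), mix)$label, "insertion")
  ## stratification bed outranks the indel classes
  strat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(35, 45))
  expect_identical(labelRegions(mk_window(1), mix, stratBeds = strat)$label,
                   "low_complexity_or_poor_mappability")
})

test_that("windows crossing a variant span or outside the bed are excluded", {
  v <- data.frame(chrom = "chr1", pos = 148L, ref = "AGGG", alt = "A",
                  gt = "0|1")
  expect_identical(nrow(labelRegions(mk_window(1), v)), 0L)  # span crosses 150
  bed <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 400))
  expect_identical(nrow(labelRegions(mk_window(1), v[0, ], bed)), 0L)
})

test_that("targets are exact-length edits of the reference", {
  w <- mk_window(10)
  none <- data.frame(chrom = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     gt = character(0))
  tg <- buildTargets(w, none, refseq300)
  expect_identical(tg$hap0, substr(refseq300, 10, 157))
  expect_identical(tg$hap0, tg$hap1)
  ## phased het SNV on haplotype 1 only
  v <- data.frame(chrom = "chr1", pos = 20L,
                  ref = substr(refseq300, 20, 20), alt = "X", gt = "0|1")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1L]
  tg <- buildTargets(w, v, refseq300)
  expect_identical(tg$hap0, substr(refseq300, 10, 157))
  expect_identical(substr(tg$hap1, 11, 11), v$alt)
  ## homozygous variants appear on both
  v$gt <- "1|1"
  tg <- buildTargets(w, v, refseq300)
  expect_identical(tg$hap0, tg$hap1)
  ## a 3 bp deletion shortens the edit, re-extended from downstream reference
  del <- data.frame(chrom = "chr1", pos = 30L,
                    ref = substr(refseq300, 30, 33),
                    alt = substr(refseq300, 30, 30), gt = "1|0")
  tg <- buildTargets(w, del, refseq300)
  expect_identical(nchar(tg$hap0), 148L)
  expected <- paste0(substr(refseq300, 10, 30), substr(refseq300, 34, 300))
  expect_identical(tg$hap0, substr(expected, 1, 148))   # sequence-edit oracle
  expect_identical(tg$hap1, substr(refseq300, 10, 157))
  ## unphased het genotypes are rejected
  del$gt <- "0/1"
  expect_error(buildTargets(w, del, refseq300), "resolvePhase")
})

test_that("overlapping truth variants on one haplotype are an error", {
  v <- data.frame(chrom = "chr1", pos = c(20L, 21L),
                  ref = c(substr(refseq300, 20, 24),
                          substr(refseq300, 21, 21)),
                  alt = c(substr(refseq300, 20, 20), "A"),
                  gt = c("1|1", "1|1"))
  expect_error(buildTargets(mk_window(10), v, refseq300), "overlapping")
})

test_that("read-backed phasing recovers cis and trans configurations", {
  refseq <- refseq300
  w <- mk_window(10)
  p1 <- 40L; p2 <- 60L
  b <- function(p) substr(refseq, p, p)
  alt1 <- setdiff(c("A", "C", "G", "T"), b(p1))[1L]
  alt2 <- setdiff(c("A", "C", "G", "T"), b(p2))[1L]
  v <- data.frame(chrom = "chr1", pos = c(p1, p2), ref = c(b(p1), b(p2)),
                  alt = c(alt1, alt2), gt = c("0/1", "0/1"))
  mkread <- function(start, len, alts) {
    s <- substr(refseq, start, start + len - 1L)
    for (p in alts) {
      off <- p - start + 1L
      substr(s, off, off) <- if (p == p1) alt1 else alt2
    }
    s
  }
  ## cis: half the reads carry both alts, half carry neither
  reads_cis <- mk_reads(rep(c(25L, 30L), each = 4L), "60M",
                        c(vapply(rep(25L, 4), mkread, character(1), 60L,
                                 c(p1, p2)),
                          vapply(rep(30L, 4), mkread, character(1), 60L,
                                 integer(0))))
  got <- resolvePhase(w, v, reads_cis, refseq)
  expect_identical(length(unique(got$gt)), 1L)      # both on one haplotype
  expect_true(all(got$gt %in% c("0|1", "1|0")))
  ## trans: reads carry exactly one alt each
  reads_trans <- mk_reads(rep(c(25L, 30L), each = 4L), "60M",
                          c(vapply(rep(25L, 4), mkread, character(1), 60L,
                                   p1),
                            vapply(rep(30L, 4), mkread, character(1), 60L,
                                   p2)))
  got <- resolvePhase(w, v, reads_trans, refseq)
  expect_identical(sort(got$gt), c("0|1", "1|0"))   # opposite haplotypes
})

test_that("single heterozygous variants go to haplotype 1", {
  v <- data.frame(chrom = "chr1", pos = 40L,
                  ref = substr(refseq300, 40, 40), alt = "A", gt = "0/1")
  if (v$ref == "A") v$alt <- "C"
  reads <- mk_tiling_reads(refseq300)
  got <- resolvePhase(mk_window(10), v, reads, refseq300)
  expect_identical(got$gt, "0|1")
})

test_that("unresolvable phase configurations are signalled", {
  b <- function(p) substr(refseq300, p, p)
  far <- data.frame(chrom = "chr1", pos = c(40L, 141L),
                    ref = c(b(40L), b(141L)), alt = c("A", "A"),
                    gt = c("0/1", "0/1"))
  far$alt[far$ref == "A"] <- "C"
  expect_null(resolvePhase(mk_window(10), far, mk_tiling_reads(refseq300),
                           refseq300))
  near <- data.frame(chrom = "chr1", pos = c(40:44),
                     ref = vapply(40:44, b, character(1)),
                     alt = "N", gt = "0/1")
  near$alt <- ifelse(near$ref == "A", "C", "A")
  expect_null(resolvePhase(mk_window(10), near, mk_tiling_reads(refseq300),
                           refseq300, maxEnum = 4L))
})
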
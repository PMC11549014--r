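test_that("a zero-rate configuration yields pure reference reads", {
  s <- simulateSample(simConfig(refLength = 3000, snvRate = 0, insRate = 0,
                                delRate = 0, baseError = 0,
                                readIndelError = 0, seed = 5))
  expect_identical(nrow(s@truth), 0L)
  expect_true(all(s@reads$cigar == "150M"))
  refseq <- s@reference[["contig1"]]
  same <- mapply(function(p, sq) substr(refseq, p, p + 149L) == sq,
                 s@reads$pos, s@reads$seq)
  expect_true(all(same))
})

test_that("simulation is exactly reproducible from config + seed", {
  cfg <- simConfig(refLength = 4000, seed = 77)
  a <- simulateSample(cfg)
  b <- simulateSample(cfg)
  expect_identical(a@reference, b@reference)
  expect_identical(a@truth, b@truth)
  expect_identical(a@reads, b@reads)
  c <- simulateSample(simConfig(refLength = 4000, seed = 78))
  expect_false(identical(a@reference, c@reference))
})

test_that("error-free reads are internally consistent with their CIGARs", {
  s <- cached_sim("sim_consistent",
                  simulateSample(simConfig(refLength = 8000, baseError = 0,
                                           readIndelError = 0, seed = 13)))
  ## CIGAR read-consumed length always equals the sequence length
  co <- lapply(s@reads$cigar, hapformer:::.cigar_ops)
  rlen <- vapply(co, function(x)
    sum(x$len[x$op %in% c("M", "I", "S", "=", "X")]), integer(1))
  expect_identical(rlen, nchar(s@reads$seq))
  ## aligned (M) bases equal the reference except at planted variant sites
  refseq <- s@reference[["contig1"]]
  tpos <- s@truth$pos
  vspan <- unlist(mapply(function(p, r) p:(p + nchar(r)), s@truth$pos,
                         s@truth$ref))
  for (i in sample(nrow(s@reads), 200)) {
    ev <- hapformer:::.read_events(s@reads$pos[i], s@reads$cigar[i],
                                   s@reads$seq[i], s@reads$qual[i], "+",
                                   60L, s@reads$pos[i],
                                   s@reads$pos[i] + 200L)
    m <- ev$feat[, 6] == 1 & ev$feat[, 7] == 1
    cols <- ev$cols[m] + s@reads$pos[i] - 1L
    base <- c("A", "C", "G", "T")[max.col(ev$feat[m, 1:4, drop = FALSE])]
    refb <- strsplit(substr(refseq, min(cols), max(cols)), "")[[1L]]
    mismatch <- cols[base != refb[cols - min(cols) + 1L]]
    expect_true(all(mismatch %in% vspan),
                info = paste("read", i))
  }
})

test_that("coverage matches the configured depth", {
  s <- cached_sim("sim_consistent",
                  simulateSample(simConfig(refLength = 8000, baseError = 0,
                                           readIndelError = 0, seed = 13)))
  depth <- sum(nchar(s@reads$seq)) / nchar(s@reference[["contig1"]])
  expect_lt(abs(depth / 50 - 1), 0.05)
})

test_that("heterozygous sites show balanced allele fractions at depth", {
  ## pooled alt fraction over replicate simulations, binomial around 0.5
  fracs <- c()
  for (seed in 1:40) {
    s <- simulateSample(simConfig(refLength = 1500, snvRate = 2e-3,
                                  insRate = 0, delRate = 0, hetFraction = 1,
                                  baseError = 0, seed = seed))
    if (nrow(s@truth) == 0L) next
    refseq <- s@reference[["contig1"]]
    for (vi in seq_len(nrow(s@truth))) {
      pos <- s@truth$pos[vi]
      sel <- s@reads$pos <= pos & s@reads$rend >= pos
      bases <- substr(s@reads$seq[sel], pos - s@reads$pos[sel] + 1L,
                      pos - s@reads$pos[sel] + 1L)
      fracs <- c(fracs, mean(bases == s@truth$alt[vi]))
    }
  }
  expect_gt(length(fracs), 30)
  expect_lt(abs(mean(fracs) - 0.5), 0.15)
})

test_that("written FASTA/VCF/BAM round-trip through standard readers", {
  s <- cached_sim("sim_io", simulateSample(simConfig(refLength = 3000,
                                                     seed = 41)))
  dir <- tempfile("simio")
  paths <- writeSample(s, dir, bgzipVcf = TRUE)
  expect_true(all(file.exists(paths$fasta, paths$vcf, paths$bam,
                              paste0(paths$fasta, ".fai"),
                              paste0(paths$bam, ".bai"), paths$vcf_gz)))
  fa <- Biostrings::readDNAStringSet(paths$fasta)
  expect_identical(as.character(fa[["contig1"]]), s@reference[["contig1"]])
  tv <- readVcfAsCalls(paths$vcf)
  expect_identical(tv$pos, s@truth$pos)
  expect_identical(tv$ref, s@truth$ref)
  expect_identical(tv$alt, s@truth$alt)
  expect_identical(tv$gt, s@truth$gt)
  cnt <- Rsamtools::countBam(paths$bam)$records
  expect_identical(cnt, nrow(s@reads))
  unlink(dir, recursive = TRUE)
})

test_that("region suites honor class requests and target construction", {
  s <- cached_sim("sim_io", simulateSample(simConfig(refLength = 3000,
                                                     seed = 41)))
  suite <- makeRegionSuite(s, maxReads = 16, seed = 2,
                           classCounts = c(true_negative = 5L))
  labs <- vapply(suite, `[[`, character(1), "label")
  expect_identical(sum(labs == "true_negative"), 5L)
  tn <- suite[labs == "true_negative"]
  for (ex in tn) {
    refslice <- substr(s@reference[[ex$chrom]], ex$start, ex$start + 147L)
    expect_identical(detokenize(ex$t0), refslice)   # targets equal reference
    expect_identical(detokenize(ex$t1), refslice)
  }
  ## every example has exactly 37 tokens per haplotype
  expect_true(all(vapply(suite, function(e)
    length(e$t0) == 37L && length(e$t1) == 37L, logical(1))))
})

test_that("planted variants are recovered by diffing targets (round trip)", {
  s <- cached_sim("sim_io", simulateSample(simConfig(refLength = 3000,
                                                     seed = 41)))
  suite <- makeRegionSuite(s, maxReads = 16, seed = 2, replicates = 1)
  labs <- vapply(suite, `[[`, character(1), "label")
  found <- character(0)
  for (ex in suite[labs != "true_negative"]) {
    refseq <- s@reference[[ex$chrom]]
    refslice <- substr(refseq, ex$start, ex$start + 200L)
    for (t in list(ex$t0, ex$t1)) {
      v <- extractVariants(detokenize(t), refslice, sliceStart = ex$start)
      if (nrow(v))
        found <- c(found, paste(ex$chrom, v$pos, v$ref, v$alt))
    }
  }
  truth_keys <- paste(s@truth$chrom, s@truth$pos, s@truth$ref, s@truth$alt)
  ## every planted variant inside some emitted window is recovered exactly
  expect_true(all(unique(found) %in% truth_keys))
  expect_gt(length(intersect(unique(found), truth_keys)), 0L)
})
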
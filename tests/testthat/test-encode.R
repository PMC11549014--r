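test_that("base feature vectors follow the 10-feature layout", {
  expect_equal(baseFeatures("C", 30, "aligned", FALSE, FALSE, 60),
               c(0, 1, 0, 0, 0.30, 1, 1, 0, 0, 0.60))
  ## deletions carry no base or base quality, only the consumes-ref flag
  expect_equal(baseFeatures(type = "deletion", reverseStrand = TRUE,
                            clipped = TRUE, mapq = 60),
               c(0, 0, 0, 0, 0, 1, 0, 1, 1, 0.60))
  ## insertion bases consume the read but not the reference
  expect_equal(baseFeatures("G", 20, "insertion", FALSE, FALSE, 40),
               c(0, 0, 1, 0, 0.20, 0, 1, 0, 0, 0.40))
  ## N encodes as all-zero one-hot with flags intact
  expect_equal(baseFeatures("N", 10, "aligned", FALSE, FALSE, 60)[1:4],
               c(0, 0, 0, 0))
  expect_error(baseFeatures("Z", 10, "aligned"), "cannot encode")
})

test_that("a zero-read window encodes only the reference row", {
  ref <- mk_ref(400, seed = 2)
  er <- encodeRegion(mk_reads(integer(0), character(0), character(0)),
                     ref, mk_window(100), maxReads = 32)
  a <- regionArray(er)
  expect_identical(dim(a), c(150L, 32L, 10L))
  expect_true(all(a[, 2:32, ] == 0))
  ## reference row: one-hot + quality 1.0, no flags
  expect_true(all(rowSums(a[, 1, 1:4]) == 1))
  expect_true(all(a[, 1, 5] == 1))
  expect_true(all(a[, 1, 6:10] == 0))
  expect_identical(length(readIds(er)), 0L)
})

test_that("read placement matches the CIGAR walk", {
  ref <- mk_ref(400, seed = 2)
  refseq <- ref[["chr1"]]
  ## 10M read spanning columns 1-10 of the window
  rd <- mk_reads(100, "10M", substr(refseq, 100, 109))
  er <- encodeRegion(rd, ref, mk_window(100), maxReads = 8)
  a <- regionArray(er)
  nz <- which(apply(a[, 2, ] != 0, 1, any))
  expect_identical(nz, 1:10)
  ## 5M2D5M: columns 6-7 are deletion events
  rd <- mk_reads(100, "5M2D5M", paste0(substr(refseq, 100, 104),
                                       substr(refseq, 107, 111)))
  er <- encodeRegion(rd, ref, mk_window(100), maxReads = 8)
  a <- regionArray(er)
  expect_true(all(a[6:7, 2, 1:4] == 0))      # no base one-hot
  expect_equal(a[6:7, 2, 6], c(1, 1))        # consumes reference
  expect_equal(a[6:7, 2, 7], c(0, 0))        # does not consume read
  ## insertion: first inserted base encoded at the anchor column
  rd <- mk_reads(100, "5M2I5M", paste0(substr(refseq, 100, 104), "GG",
                                       substr(refseq, 105, 109)))
  er <- encodeRegion(rd, ref, mk_window(100), maxReads = 8)
  a <- regionArray(er)
  expect_equal(a[5, 2, 6], 0)                # anchor col: consumes_ref = 0
  expect_equal(a[5, 2, 7], 1)
  expect_equal(a[5, 2, 3], 1)                # the G one-hot
  nz <- which(apply(a[, 2, ] != 0, 1, any))
  expect_identical(nz, 1:10)                 # ref span unchanged
})

test_that("nonzero columns equal an independent CIGAR interpreter's span", {
  ref <- mk_ref(600, seed = 5)
  refseq <- ref[["chr1"]]
  set.seed(9)
  cigars <- c("20M", "5S15M", "10M3D10M", "8M2I10M", "4M1D4M1I4M2S",
              "30M", "12M5D3M", "3S5M4I8M")
  for (i in seq_along(cigars)) {
    pos <- sample(120:200, 1)
    rlen <- sum(hapformer:::.cigar_ops(cigars[i])$len *
                  (hapformer:::.cigar_ops(cigars[i])$op %in%
                     c("M", "I", "S", "=", "X")))
    rd <- mk_reads(pos, cigars[i],
                   paste(sample(c("A", "C", "G", "T"), rlen, TRUE),
                         collapse = ""))
    er <- encodeRegion(rd, ref, mk_window(100), maxReads = 8)
    nz <- which(apply(regionArray(er)[, 2, ] != 0, 1, any))
    expect_identical(nz, oracle_read_columns(pos, cigars[i], 100L, 249L),
                     info = cigars[i])
  }
})

test_that("reads are sorted by first aligned base and capped at r-1", {
  ref <- mk_ref(400, seed = 2)
  refseq <- ref[["chr1"]]
  rd <- mk_reads(c(110, 105, 107), rep("20M", 3),
                 substring(refseq, c(110, 105, 107),
                           c(129, 124, 126)))
  got <- extractReads(rd, mk_window(100), maxReads = 150)
  expect_identical(got$pos, c(105L, 107L, 110L))
  ## downsampling: 200 overlapping reads, r = 150 -> 149 kept, order intact
  rd <- mk_reads(rep(101:120, each = 10), "30M",
                 substring(refseq, rep(101:120, each = 10),
                           rep(130:149, each = 10)))
  got <- extractReads(rd, mk_window(100), maxReads = 150L, seed = 1)
  expect_identical(nrow(got), 149L)
  expect_true(!is.unsorted(got$pos))
})

test_that("seeded downsampling is reproducible and uniform", {
  ref <- mk_ref(500, seed = 3)
  refseq <- ref[["chr1"]]
  rd <- mk_reads(rep(101:150, 6), "30M",
                 substring(refseq, rep(101:150, 6), rep(130:179, 6)))
  w <- mk_window(120)
  a <- extractReads(rd, w, maxReads = 150L, seed = 42)
  b <- extractReads(rd, w, maxReads = 150L, seed = 42)
  expect_identical(a, b)
  c <- extractReads(rd, w, maxReads = 150L, seed = 43)
  expect_false(identical(a$qname, c$qname))
  ## uniformity: inclusion frequency of each read ~ 149/300 over seeded trials
  counts <- integer(nrow(rd))
  names(counts) <- rd$qname
  trials <- 500L
  for (s in seq_len(trials)) {
    got <- extractReads(rd, w, maxReads = 150L, seed = s)
    counts[got$qname] <- counts[got$qname] + 1L
  }
  freq <- counts / trials
  expect_true(all(abs(freq - 149 / 300) < 0.10))
  expect_equal(mean(freq), 149 / 300, tolerance = 1e-6)
})

test_that("encoding is deterministic and windows clip at contig ends", {
  ref <- mk_ref(200, seed = 4)
  rd <- mk_tiling_reads(ref[["chr1"]])
  w <- mk_window(30)
  e1 <- encodeRegion(rd, ref, w, maxReads = 16, seed = 9)
  e2 <- encodeRegion(rd, ref, w, maxReads = 16, seed = 9)
  expect_identical(regionArray(e1), regionArray(e2))
  ## window past the contig end: clipped and zero-padded with a warning
  expect_warning(er <- encodeRegion(rd, ref, mk_window(101), maxReads = 16),
                 "clipped")
  a <- regionArray(er)
  expect_identical(dim(a), c(150L, 16L, 10L))
  expect_true(all(a[101:150, 1, ] == 0))
  expect_error(encodeRegion(rd, ref, mk_window(10, chrom = "chrX"),
                            maxReads = 16),
               "contig not found")
})

test_that("encoding from BAM matches encoding from the in-memory reads", {
  s <- cached_sim("enc_bam", simulateSample(simConfig(refLength = 3000,
                                                      seed = 77)))
  dir <- tempfile("simout")
  paths <- writeSample(s, dir)
  expect_true(file.exists(paths$bam))
  w <- mk_window(1200, chrom = "contig1")
  e_mem <- encodeRegion(s@reads, s@reference, w, maxReads = 32, seed = 5)
  e_bam <- encodeRegion(paths$bam, paths$fasta, w, maxReads = 32, seed = 5)
  expect_identical(regionArray(e_mem), regionArray(e_bam))
  expect_identical(readIds(e_mem), readIds(e_bam))
  unlink(dir, recursive = TRUE)
})
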
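## shared in-code fixtures

## a minimal in-memory read table
mk_reads <- function(pos, cigar, seq, chrom = "chr1", qual = NULL,
                     strand = "+", mapq = 60L) {
  n <- length(pos)
  if (is.null(qual))
    qual <- vapply(nchar(gsub("[^ACGTN]", "", seq)), function(k)
      paste(rep("I", k), collapse = ""), character(1))   # phred 40
  data.frame(qname = sprintf("r%03d", seq_len(n)),
             chrom = rep_len(chrom, n),
             pos = as.integer(pos), cigar = cigar, seq = seq, qual = qual,
             strand = rep_len(strand, n), mapq = rep_len(as.integer(mapq), n),
             stringsAsFactors = FALSE)
}

mk_window <- function(start, chrom = "chr1", width = 150L) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width))
}

## deterministic random reference
mk_ref <- function(len, seed = 1, chrom = "chr1") {
  set.seed(seed)
  r <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  stats::setNames(r, chrom)
}

## perfect (error-free) reads tiling a contig at a given depth
mk_tiling_reads <- function(refseq, chrom = "chr1", read_len = 50L,
                            step = 10L) {
  L <- nchar(refseq)
  starts <- seq(1L, L - read_len + 1L, by = step)
  mk_reads(starts, paste0(read_len, "M"),
           substring(refseq, starts, starts + read_len - 1L), chrom = chrom)
}

## a small simulated sample, cached per test run
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (is.null(sim_cache[[key]])) sim_cache[[key]] <- force(expr)
  sim_cache[[key]]
}
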
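#' Simulation configuration
#'
#' Parameters of the diploid read simulator. Defaults emulate the data the
#' caller is designed for: 150 bp reads at 50x total depth (25x per
#' haplotype), a human-like variant load (1 SNV per kb, indels at an eighth of
#' that rate with short geometric lengths, two-thirds heterozygous) and a 0.1%
#' base-call error rate.
#'
#' @param refLength contig length in bp.
#' @param nContigs number of contigs (named `contig1`, `contig2`, ...).
#' @param gc GC fraction of the random reference.
#' @param snvRate,insRate,delRate per-bp variant planting rates.
#' @param indelGeomP geometric length parameter (mean length `1/p`).
#' @param maxIndel maximum planted indel length.
#' @param hetFraction fraction of planted variants that are heterozygous.
#' @param readLength read length in bp.
#' @param depth mean total coverage (haplotypes each sequenced at `depth/2`).
#' @param baseError per-base substitution error rate in reads.
#' @param readIndelError per-base rate of single-base indel errors in reads.
#' @param qualMean,qualSd phred base-quality profile (clamped to [2, 40]).
#' @param seed mandatory RNG seed.
#' @return a validated config list of class `simConfig`.
#' @export
simConfig <- function(refLength = 20000L, nContigs = 1L, gc = 0.42,
                      snvRate = 1e-3, insRate = 1.25e-4, delRate = 1.25e-4,
                      indelGeomP = 0.5, maxIndel = 20L, hetFraction = 2 / 3,
                      readLength = 150L, depth = 50, baseError = 1e-3,
                      readIndelError = 1e-5, qualMean = 35, qualSd = 3,
                      seed) {
  if (missing(seed)) stop("simConfig requires an explicit seed")
  cfg <- list(refLength = as.integer(refLength), nContigs = as.integer(nContigs),
              gc = gc, snvRate = snvRate, insRate = insRate, delRate = delRate,
              indelGeomP = indelGeomP, maxIndel = as.integer(maxIndel),
              hetFraction = hetFraction, readLength = as.integer(readLength),
              depth = depth, baseError = baseError,
              readIndelError = readIndelError,
              qualMean = qualMean, qualSd = qualSd, seed = as.integer(seed))
  rates <- c(cfg$gc, cfg$snvRate, cfg$insRate, cfg$delRate, cfg$hetFraction,
             cfg$baseError, cfg$readIndelError)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$depth <= 0) stop("depth must be positive")
  class(cfg) <- "simConfig"
  cfg
}

.rand_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## plant non-overlapping, left-normalized variants on one contig
.plant_variants <- function(refseq, cfg) {
  L <- nchar(refseq)
  margin <- cfg$readLength + cfg$maxIndel + 10L
  lo <- 2L; hi <- L - margin
  if (hi <= lo) return(data.frame(pos = integer(0), ref = character(0),
                                  alt = character(0), gt = character(0)))
  n_snv <- stats::rbinom(1L, L, cfg$snvRate)
  n_ins <- stats::rbinom(1L, L, cfg$insRate)
  n_del <- stats::rbinom(1L, L, cfg$delRate)
  bases <- c("A", "C", "G", "T")
  taken <- integer(0)   # occupied reference positions (with 1bp buffer)
  out <- list()
  mk <- function(type) {
    for (try in 1:200) {
      pos <- sample(lo:hi, 1L)
      len <- if (type == "snv") 1L else
        min(cfg$maxIndel, 1L + stats::rgeom(1L, cfg$indelGeomP))
      span <- if (type == "del") pos:(pos + len) else pos
      if (type == "ins") span <- pos:(pos + 1L)
      if (any(span %in% taken)) next
      rb <- substr(refseq, pos, pos)
      if (type == "snv") {
        alt <- sample(setdiff(bases, rb), 1L)
        v <- list(pos = pos, ref = rb, alt = alt)
      } else if (type == "ins") {
        insseq <- paste(sample(bases, len, replace = TRUE), collapse = "")
        v <- leftNormalize(pos, rb, paste0(rb, insseq), refseq)
      } else {
        delseq <- substr(refseq, pos + 1L, pos + len)
        v <- leftNormalize(pos, paste0(rb, delseq), rb, refseq)
      }
      ## occupied span after normalization, with a 1 bp buffer on each side
      vspan <- (v$pos - 1L):(v$pos + nchar(v$ref))
      if (any(vspan %in% taken) || v$pos < 2L) next
      taken <<- c(taken, vspan)
      return(v)
    }
    NULL   # could not place without collision; contig too dense
  }
  for (type in c(rep("del", n_del), rep("ins", n_ins), rep("snv", n_snv))) {
    v <- mk(type)
    if (!is.null(v)) out[[length(out) + 1L]] <- v
  }
  if (!length(out))
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), gt = character(0)))
  df <- do.call(rbind, lapply(out, function(v)
    data.frame(pos = v$pos, ref = v$ref, alt = v$alt)))
  df$gt <- ifelse(stats::runif(nrow(df)) < cfg$hetFraction,
                  ifelse(stats::runif(nrow(df)) < 0.5, "0|1", "1|0"),
                  "1|1")
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## apply the variants carried by one haplotype; returns the haplotype sequence
## and, per haplotype base, the reference position it aligns to (0 for
## inserted bases)
.apply_variants <- function(refseq, vars) {
  L <- nchar(refseq)
  if (nrow(vars) == 0L)
    return(list(seq = refseq, map = seq_len(L)))
  pieces <- character(0)
  maps <- list()
  cursor <- 1L
  for (i in seq_len(nrow(vars))) {
    pos <- vars$pos[i]; ref <- vars$ref[i]; alt <- vars$alt[i]
    if (pos < cursor) stop("overlapping variants on one haplotype")
    if (pos > cursor) {
      pieces <- c(pieces, substr(refseq, cursor, pos - 1L))
      maps[[length(maps) + 1L]] <- cursor:(pos - 1L)
    }
    pieces <- c(pieces, alt)
    nr <- nchar(ref); na <- nchar(alt)
    shared <- min(nr, na)      # leading shared context maps to reference
    m <- c(pos:(pos + shared - 1L), rep(0L, max(0L, na - shared)))
    maps[[length(maps) + 1L]] <- m
    cursor <- pos + nr
  }
  if (cursor <= L) {
    pieces <- c(pieces, substr(refseq, cursor, L))
    maps[[length(maps) + 1L]] <- cursor:L
  }
  list(seq = paste(pieces, collapse = ""), map = unlist(maps))
}

## alignment record for a read spanning haplotype positions [s, e];
## leading/trailing inserted bases are soft-clipped
.read_alignment <- function(map, s, e) {
  refp <- map[s:e]
  aligned <- which(refp > 0L)
  if (length(aligned) == 0L) return(NULL)   # read entirely inside insertion
  n <- length(refp)
  lens <- integer(0); ops <- character(0)
  add <- function(op, len) { ops <<- c(ops, op); lens <<- c(lens, len) }
  lead <- aligned[1L] - 1L
  trail <- n - aligned[length(aligned)]
  if (lead > 0L) add("S", lead)
  ai <- aligned
  ri <- refp[ai]
  z <- diff(ai) - 1L       # inserted bases between consecutive aligned bases
  dg <- diff(ri) - 1L      # deleted reference bases between them
  breaks <- which(z > 0L | dg > 0L)
  prev <- 1L
  for (b in breaks) {
    add("M", b - prev + 1L)
    if (z[b] > 0L) add("I", z[b])
    if (dg[b] > 0L) add("D", dg[b])
    prev <- b + 1L
  }
  add("M", length(ai) - prev + 1L)
  if (trail > 0L) add("S", trail)
  list(pos = ri[1L], cigar = .cigar_string(lens, ops))
}

## inject a single-base insertion or deletion sequencing error
.inject_read_indel <- function(seq, cigar, pos0) {
  co <- .cigar_ops(cigar)
  ## expand to alignment columns: op per column, read-consuming flag
  op <- rep(co$op, co$len)
  reads <- op %in% c("M", "=", "X", "I", "S")
  read_idx <- cumsum(reads)
  n <- nchar(seq)
  at <- max(2L, min(n - 1L, pos0))
  col <- which(reads & read_idx == at)[1L]
  if (is.na(col)) return(list(seq = seq, cigar = cigar))
  if (stats::runif(1L) < 0.5) {            # insertion error
    base <- sample(c("A", "C", "G", "T"), 1L)
    seq <- paste0(substr(seq, 1L, at), base, substr(seq, at + 1L, n))
    op <- append(op, "I", after = col)
  } else {                                 # deletion error
    if (op[col] == "M") op[col] <- "D"
    else op <- op[-col]
    seq <- paste0(substr(seq, 1L, at - 1L), substr(seq, at + 1L, n))
  }
  ## cannot start/end with D after edits at interior positions (at >= 2)
  rl <- rle(op)
  list(seq = seq, cigar = .cigar_string(rl$lengths, rl$values))
}

#' Simulate a diploid sample
#'
#' Generates a random reference, plants phased variants to derive two
#' haplotypes per contig, and draws error-bearing reads uniformly from each
#' haplotype at half the configured depth. Read alignments (POS/CIGAR) are
#' derived exactly from the known haplotype-to-reference edit script, then
#' sequencing errors are injected, so alignments are internally consistent by
#' construction.
#'
#' @param config a [simConfig()].
#' @return a [SimulatedSample-class].
#' @examples
#' s <- simulateSample(simConfig(refLength = 3000, seed = 1))
#' s
#' @export
simulateSample <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  .with_seed(config$seed, {
    refs <- character(0)
    truth <- list(); reads <- list(); haps <- list()
    bases <- c("A", "C", "G", "T")
    for (ci in seq_len(config$nContigs)) {
      contig <- paste0("contig", ci)
      refseq <- .rand_seq(config$refLength, config$gc)
      refs[[contig]] <- refseq
      vars <- .plant_variants(refseq, config)
      if (nrow(vars)) vars <- cbind(chrom = contig, vars)
      else vars <- data.frame(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0),
                              gt = character(0))
      truth[[contig]] <- vars
      a0 <- as.integer(substr(vars$gt, 1L, 1L))
      a1 <- as.integer(substr(vars$gt, 3L, 3L))
      h0 <- .apply_variants(refseq, vars[a0 == 1L, , drop = FALSE])
      h1 <- .apply_variants(refseq, vars[a1 == 1L, , drop = FALSE])
      haps[[contig]] <- list(h0 = h0, h1 = h1)
      rl <- config$readLength
      for (h in 0:1) {
        hp <- if (h == 0L) h0 else h1
        hapL <- nchar(hp$seq)
        nread <- round(config$depth / 2 * hapL / rl)
        starts <- sample.int(hapL - rl + 1L, nread, replace = TRUE)
        ends <- starts + rl - 1L
        ## haplotype positions where the reference alignment is not a plain
        ## match continuation; reads avoiding them are pure 150M
        special <- which(hp$map == 0L |
                         c(TRUE, diff(hp$map) != 1L))
        special <- special[special > 1L | hp$map[1L] != 1L]
        sq <- substring(hp$seq, starts, ends)
        pos <- hp$map[starts]
        cg <- rep(paste0(rl, "M"), nread)
        irregular <- which(
          vapply(seq_len(nread), function(i)
            any(special > starts[i] & special <= ends[i]) ||
              hp$map[starts[i]] == 0L, logical(1)))
        drop <- logical(nread)
        for (i in irregular) {
          al <- .read_alignment(hp$map, starts[i], ends[i])
          if (is.null(al)) { drop[i] <- TRUE; next }
          pos[i] <- al$pos; cg[i] <- al$cigar
        }
        ## substitution errors
        nerr <- stats::rbinom(nread, rl, config$baseError)
        for (i in which(nerr > 0L)) {
          at <- sample.int(rl, nerr[i])
          sv <- strsplit(sq[i], "")[[1L]]
          for (p in at) sv[p] <- sample(setdiff(bases, sv[p]), 1L)
          sq[i] <- paste(sv, collapse = "")
        }
        ## single-base indel errors
        nind <- stats::rbinom(nread, rl, config$readIndelError)
        for (i in which(nind > 0L)) {
          ir <- .inject_read_indel(sq[i], cg[i], sample.int(nchar(sq[i]), 1L))
          sq[i] <- ir$seq; cg[i] <- ir$cigar
        }
        qlen <- nchar(sq)
        qual <- vapply(qlen, function(k)
          intToUtf8(pmin(40L, pmax(2L, round(stats::rnorm(k, config$qualMean,
                                                          config$qualSd)))) +
                    33L),
          character(1))
        keep <- !drop
        reads[[paste0(contig, "_h", h)]] <- data.frame(
          qname = sprintf("sim_%s_h%d_%05d", contig, h, seq_len(nread))[keep],
          chrom = contig, pos = pos[keep], cigar = cg[keep], seq = sq[keep],
          qual = qual[keep],
          strand = sample(c("+", "-"), nread, replace = TRUE)[keep],
          mapq = 60L, hap = h, stringsAsFactors = FALSE)
      }
    }
    truth_df <- do.call(rbind, truth)
    rownames(truth_df) <- NULL
    reads_df <- do.call(rbind, reads)
    reads_df <- reads_df[order(reads_df$chrom, reads_df$pos), , drop = FALSE]
    rownames(reads_df) <- NULL
    ## cache the rightmost aligned position (avoids re-walking CIGARs on
    ## every window fetch)
    reads_df$rend <- reads_df$pos + vapply(reads_df$cigar, .cigar_ref_width,
                                           integer(1), USE.NAMES = FALSE) - 1L
    new("SimulatedSample", reference = refs, truth = truth_df,
        reads = reads_df, haps = haps, config = unclass(config))
  })
}

#' Write a simulated sample to standard files
#'
#' Emits `ref.fa` (+ `.fai`), `truth.vcf` with phased genotypes (optionally
#' bgzipped + tabix-indexed) and a coordinate-sorted, indexed `reads.bam`.
#'
#' @param sample a [SimulatedSample-class].
#' @param dir output directory (created if needed).
#' @param bgzipVcf also write `truth.vcf.gz` + `.tbi`.
#' @return named list of file paths.
#' @export
writeSample <- function(sample, dir, bgzipVcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "ref.fa")
  dna <- Biostrings::DNAStringSet(sample@reference)
  Biostrings::writeXStringSet(dna, fa)
  Rsamtools::indexFa(fa)
  vcf <- file.path(dir, "truth.vcf")
  writeVcfFile(sample@truth, vcf, reference = sample@reference,
               sampleName = "simulated")
  bam <- .write_bam(sample@reads, sample@reference, file.path(dir, "reads"))
  out <- list(fasta = fa, vcf = vcf, bam = bam)
  if (bgzipVcf) {
    gz <- Rsamtools::bgzip(vcf, overwrite = TRUE)
    Rsamtools::indexTabix(gz, format = "vcf")
    out$vcf_gz <- gz
  }
  out
}

## write a read table as sorted+indexed BAM via a temporary SAM
.write_bam <- function(reads, reference, stem) {
  sam <- paste0(stem, ".sam")
  con <- file(sam, "w")
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ctg in names(reference))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg, nchar(reference[[ctg]])), con)
  if (nrow(reads)) {
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       reads$qname, flag, reads$chrom, reads$pos, reads$mapq,
                       reads$cigar, reads$seq, reads$qual), con)
  }
  close(con)
  bam0 <- Rsamtools::asBam(sam, paste0(stem, "_unsorted"), overwrite = TRUE,
                           indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(bam0, stem)
  Rsamtools::indexBam(sorted)
  unlink(c(sam, bam0))
  sorted
}

#' Build a labeled training-example suite from a simulated sample
#'
#' Emits encoded windows with phased target token sequences, mirroring the
#' calling procedure's window placement: for every cluster of planted variants
#' the windows step by `stepSize` starting `upstream` bases before the first
#' variant (so variants appear at the same window offsets seen during
#' calling), and each window is re-emitted `replicates` times with fresh read
#' downsampling. True-negative windows are tiled between variants.
#'
#' @param sample a [SimulatedSample-class].
#' @param maxReads read rows `r` of the encoded regions.
#' @param seed seed for downsampling and subsetting.
#' @param replicates fresh-downsampling copies of each variant window.
#' @param classCounts optional named integer vector capping the number of
#'   windows per label (e.g. `c(true_negative = 100)`); classes absent from
#'   the vector are kept in full.
#' @param contigs contig names to use (default all).
#' @param windowSize,targetLen window width and target length.
#' @param stepSize,upstream window placement parameters (match the caller's).
#' @return list of examples; each is a list with `region` (packed array),
#'   `t0`, `t1` (37 token ids), `label`, `chrom`, `start`, `refslice` and
#'   `sample_id`.
#' @export
makeRegionSuite <- function(sample, maxReads = 32L, seed = 0L,
                            replicates = 2L, classCounts = NULL,
                            contigs = NULL, windowSize = 150L,
                            targetLen = 148L, stepSize = 25L,
                            upstream = 100L) {
  stopifnot(is(sample, "SimulatedSample"))
  if (is.null(contigs)) contigs <- names(sample@reference)
  all_windows <- list()
  for (contig in contigs) {
    refseq <- sample@reference[[contig]]
    L <- nchar(refseq)
    max_start <- L - (targetLen + 40L)
    truth <- sample@truth[sample@truth$chrom == contig, , drop = FALSE]
    starts <- integer(0)
    if (nrow(truth)) {
      pos <- sort(truth$pos)
      cluster <- cumsum(c(1L, diff(pos) >= 100L))
      for (cl in split(pos, cluster)) {
        s <- seq(min(cl) - upstream, max(cl), by = stepSize)
        starts <- c(starts, pmax(1L, pmin(as.integer(s), max_start)))
      }
    }
    ## true-negative tiling between variants
    tn <- seq(1L, max_start, by = windowSize)
    starts <- sort(unique(c(starts, tn)))
    w <- GenomicRanges::GRanges(contig,
                                IRanges::IRanges(starts,
                                                 width = windowSize))
    lab <- labelRegions(w, truth)
    if (nrow(lab)) all_windows[[contig]] <- lab
  }
  wdf <- do.call(rbind, all_windows)
  if (is.null(wdf) || nrow(wdf) == 0L) return(list())
  rownames(wdf) <- NULL
  ## optional per-class caps (seeded, deterministic)
  if (!is.null(classCounts)) {
    keep <- .with_seed(seed + 7L, {
      unlist(lapply(split(seq_len(nrow(wdf)), wdf$label), function(ix) {
        lbl <- wdf$label[ix[1L]]
        if (lbl %in% names(classCounts) && length(ix) > classCounts[[lbl]])
          sort(sample(ix, classCounts[[lbl]]))
        else ix
      }), use.names = FALSE)
    })
    wdf <- wdf[sort(keep), , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(wdf))) {
    contig <- wdf$chrom[i]
    refseq <- sample@reference[[contig]]
    win <- GenomicRanges::GRanges(contig,
                                  IRanges::IRanges(wdf$start[i],
                                                   width = windowSize))
    truth <- sample@truth[sample@truth$chrom == contig, , drop = FALSE]
    vend <- truth$pos + nchar(truth$ref) - 1L
    v <- truth[truth$pos >= wdf$start[i] & vend <= wdf$end[i], , drop = FALSE]
    v <- resolvePhase(win, v, sample@reads[sample@reads$chrom == contig &
                                             sample@reads$pos <= wdf$end[i] &
                                             sample@reads$pos + 200L >=
                                               wdf$start[i], , drop = FALSE],
                      refseq)
    if (is.null(v)) next                      # unresolvable phase: discard
    tg <- tryCatch(buildTargets(win, v, refseq, targetLen),
                   error = function(e) NULL)
    if (is.null(tg)) next
    reps <- if (wdf$label[i] == "true_negative") 1L else replicates
    ## each replicate is freshly downsampled AND start-jittered within the
    ## window step, so repeated loci never share a tokenization frame (the
    ## large-corpus regime at small scale: every offset of a locus is its own
    ## training region)
    jit <- .with_seed(seed + 13L * i,
                      c(0L, sample.int(stepSize, reps, replace = TRUE) - 1L))
    max_start <- nchar(refseq) - (targetLen + 40L)
    for (rep in seq_len(reps)) {
      st <- min(max(1L, wdf$start[i] + jit[rep]), max_start)
      winr <- GenomicRanges::GRanges(contig,
                                     IRanges::IRanges(st, width = windowSize))
      tv <- sample@truth[sample@truth$chrom == contig, , drop = FALSE]
      tvend <- tv$pos + nchar(tv$ref) - 1L
      crossing <- (tv$pos < st & tvend >= st) |
        (tv$pos <= st + windowSize - 1L & tvend > st + windowSize - 1L)
      if (any(crossing)) next     # no well-defined target at this offset
      vr <- tv[tv$pos >= st & tvend <= st + windowSize - 1L, , drop = FALSE]
      vr <- resolvePhase(winr, vr, sample@reads[
        sample@reads$chrom == contig & sample@reads$pos <= st + 150L &
          sample@reads$pos + 200L >= st, , drop = FALSE], refseq)
      if (is.null(vr)) next
      tgr <- if (st == wdf$start[i]) tg else
        tryCatch(buildTargets(winr, vr, refseq, targetLen),
                 error = function(e) NULL)
      if (is.null(tgr)) next
      er <- encodeRegion(sample@reads, sample@reference, winr,
                         maxReads = maxReads,
                         seed = seed + 7919L * rep)
      out[[length(out) + 1L]] <- list(
        region = .pack_region(er@array),
        t0 = tokenize(tgr$hap0), t1 = tokenize(tgr$hap1),
        label = wdf$label[i], chrom = contig, start = st,
        refslice = substr(refseq, st, st + targetLen + 30L),
        sample_id = "simulated")
    }
  }
  out
}
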
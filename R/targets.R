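#' Label candidate training windows by variant content
#'
#' Tiles or accepts a set of fixed-width windows and labels each one of
#' `multi_indel`, `low_complexity_or_poor_mappability`, `insertion`,
#' `deletion`, `snv` or `true_negative`, with that precedence when a window
#' matches several classes. Windows are excluded (not labeled) when they fall
#' outside the confident regions, or when a truth variant's reference span
#' crosses the window boundary (such windows have no well-defined target).
#'
#' @param windows `GRanges` of candidate windows (all the same width).
#' @param truth data.frame of truth variants (chrom, pos, ref, alt, gt).
#' @param confidentBed optional `GRanges`; windows must fall entirely inside.
#' @param stratBeds optional `GRanges` (or list of them) marking
#'   low-complexity / poor-mappability stratifications.
#' @return data.frame with chrom, start, end (1-based inclusive), label, and
#'   n_var, the number of truth variants contained.
#' @export
labelRegions <- function(windows, truth, confidentBed = NULL,
                         stratBeds = NULL) {
  stopifnot(is(windows, "GRanges"))
  if (!is.null(stratBeds) && is.list(stratBeds))
    stratBeds <- do.call(c, stratBeds)
  if (!is.null(confidentBed)) {
    within <- IRanges::overlapsAny(windows, confidentBed, type = "within")
    windows <- windows[within]
  }
  out <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[i]
    chrom <- as.character(seqnames(w))
    v <- truth[truth$chrom == chrom, , drop = FALSE]
    vend <- v$pos + nchar(v$ref) - 1L
    inside <- v$pos >= start(w) & vend <= end(w)
    crossing <- (v$pos < start(w) & vend >= start(w)) |
      (v$pos <= end(w) & vend > end(w))
    if (any(crossing)) next                       # boundary-crossing variant
    v <- v[inside, , drop = FALSE]
    n_indel <- sum(nchar(v$ref) != nchar(v$alt))
    is_strat <- !is.null(stratBeds) && nrow(v) > 0L &&
      any(IRanges::overlapsAny(
        GenomicRanges::GRanges(chrom, IRanges::IRanges(v$pos, v$pos +
                                                         nchar(v$ref) - 1L)),
        stratBeds))
    label <- if (n_indel >= 2L) "multi_indel"
      else if (is_strat) "low_complexity_or_poor_mappability"
      else if (any(nchar(v$alt) > nchar(v$ref))) "insertion"
      else if (any(nchar(v$ref) > nchar(v$alt))) "deletion"
      else if (nrow(v) > 0L) "snv"
      else "true_negative"
    out[[i]] <- data.frame(chrom = chrom, start = start(w), end = end(w),
                           label = label, n_var = nrow(v),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      n_var = integer(0))
  rownames(res) <- NULL
  res
}

#' Build target haplotype sequences for a window
#'
#' Inserts each haplotype's alleles into the reference starting at the window
#' start and normalizes the result to exactly `targetLen` bases (148 =
#' 37 4-mers): deletions are re-extended with downstream reference sequence,
#' insertions are trimmed. Homozygous variants appear on both targets. All
#' heterozygous genotypes must be phased (`|`); use [resolvePhase()] first.
#'
#' @param window length-1 `GRanges` (the decoded window).
#' @param variants data.frame (chrom, pos, ref, alt, gt) of truth variants
#'   contained in the window, phased.
#' @param contigSeq the full contig sequence (character scalar).
#' @param targetLen target length in bases (divisible by 4).
#' @return list(hap0, hap1) of `targetLen`-base sequences.
#' @export
buildTargets <- function(window, variants, contigSeq, targetLen = 148L) {
  stopifnot(targetLen %% 4L == 0L)
  ws <- start(window)
  if (nrow(variants) > 0L) {
    if (any(!grepl("|", variants$gt, fixed = TRUE)))
      stop("unphased heterozygous genotype; run resolvePhase() first")
    variants <- variants[order(variants$pos), , drop = FALSE]
  }
  build_one <- function(carried) {
    cursor <- ws
    pieces <- character(0)
    if (nrow(carried)) {
      for (i in seq_len(nrow(carried))) {
        pos <- carried$pos[i]
        if (pos < cursor) stop("overlapping truth variants on one haplotype")
        if (pos > cursor)
          pieces <- c(pieces, substr(contigSeq, cursor, pos - 1L))
        pieces <- c(pieces, carried$alt[i])
        cursor <- pos + nchar(carried$ref[i])
      }
    }
    need <- targetLen - sum(nchar(pieces))   # bases still required
    if (need > 0L) {
      if (cursor + need - 1L > nchar(contigSeq))
        stop("window too close to contig end to build a full-length target")
      pieces <- c(pieces, substr(contigSeq, cursor, cursor + need - 1L))
    }
    substr(paste(pieces, collapse = ""), 1L, targetLen)
  }
  a0 <- if (nrow(variants)) as.integer(substr(variants$gt, 1L, 1L)) else integer(0)
  a1 <- if (nrow(variants)) as.integer(substr(variants$gt, 3L, 3L)) else integer(0)
  list(hap0 = build_one(variants[a0 == 1L, , drop = FALSE]),
       hap1 = build_one(variants[a1 == 1L, , drop = FALSE]))
}

#' Resolve the phase of unphased heterozygous variants from reads
#'
#' Enumerates all assignments of the unphased heterozygous variants to the two
#' haplotypes (2^n candidate genotypes), aligns every read to both candidate
#' haplotypes with [swAlign()], and selects the genotype maximizing the summed
#' best-alignment score. The returned pair is canonicalized so the haplotype
#' carrying fewer variants is haplotype 0 (ties broken by lexicographic
#' haplotype sequence order), so a single heterozygous variant is assigned to
#' haplotype 1. Variants 100 bp or more apart, or more than `maxEnum`
#' unphased variants, make the window unresolvable (`NULL` is returned).
#'
#' @param window length-1 `GRanges`.
#' @param variants data.frame (chrom, pos, ref, alt, gt); unphased
#'   heterozygotes carry `/` genotypes.
#' @param reads read table overlapping the window (see [extractReads()]).
#' @param contigSeq full contig sequence.
#' @param maxEnum maximum number of unphased heterozygous variants.
#' @return `variants` with all heterozygous genotypes phased (`0|1` / `1|0`),
#'   or `NULL` if the phase is unresolvable and the region should be
#'   discarded.
#' @export
resolvePhase <- function(window, variants, reads, contigSeq, maxEnum = 4L) {
  if (nrow(variants) == 0L) return(variants)
  het <- which(!variants$gt %in% c("1|1", "1/1") &
                 grepl("/", variants$gt, fixed = TRUE))
  if (length(het) == 0L) return(variants)
  hp <- variants$pos[het]
  if (length(hp) > 1L && (max(hp) - min(hp)) >= 100L) return(NULL)
  if (length(het) > maxEnum) return(NULL)
  ## phased context: already-phased variants keep their assignment
  a0 <- as.integer(substr(variants$gt, 1L, 1L))
  a1 <- as.integer(substr(variants$gt, 3L, 3L))
  lo <- max(1L, min(variants$pos) - 30L)
  hi <- min(nchar(contigSeq),
            max(variants$pos + nchar(variants$ref)) + 30L)
  hapseq <- function(carried) {
    carried <- carried[order(carried$pos), , drop = FALSE]
    cursor <- lo; pieces <- character(0)
    for (i in seq_len(nrow(carried))) {
      pos <- carried$pos[i]
      if (pos < cursor) return(NULL)      # incompatible overlap
      pieces <- c(pieces, substr(contigSeq, cursor, pos - 1L),
                  carried$alt[i])
      cursor <- pos + nchar(carried$ref[i])
    }
    paste(c(pieces, substr(contigSeq, cursor, hi)), collapse = "")
  }
  n <- length(het)
  configs <- as.matrix(expand.grid(rep(list(0:1), n)))
  best <- NULL
  for (ci in seq_len(nrow(configs))) {
    assign0 <- a0; assign1 <- a1
    assign0[het] <- configs[ci, ]
    assign1[het] <- 1L - configs[ci, ]
    h0 <- hapseq(variants[assign0 == 1L, , drop = FALSE])
    h1 <- hapseq(variants[assign1 == 1L, , drop = FALSE])
    if (is.null(h0) || is.null(h1)) next
    score <- 0
    for (ri in seq_len(nrow(reads))) {
      s0 <- swAlign(reads$seq[ri], h0)$score
      s1 <- swAlign(reads$seq[ri], h1)$score
      score <- score + max(s0, s1)
    }
    ## canonical order: fewer variants first, then lexicographic sequence
    key <- if (sum(assign0) < sum(assign1) ||
               (sum(assign0) == sum(assign1) && h0 <= h1))
      c(h0, h1) else c(h1, h0)
    swap <- !identical(key[1L], h0)
    cand <- list(score = score, key = key,
                 assign0 = if (swap) assign1 else assign0,
                 assign1 = if (swap) assign0 else assign1)
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score &&
           paste(cand$key, collapse = "\r") <
             paste(best$key, collapse = "\r")))
      best <- cand
  }
  if (is.null(best)) return(NULL)
  out <- variants
  out$gt <- paste0(best$assign0, "|", best$assign1)
  out$gt[out$gt == "1|1"] <- "1|1"
  out
}
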
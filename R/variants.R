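#' Left-normalize a variant
#'
#' Standard VCF normalization: shared trailing bases are trimmed, shared
#' leading bases are trimmed down to a single anchor base, and indels are
#' shifted left while the preceding reference base equals the last base of
#' the longer allele. `refseq` supplies upstream context for the shift.
#'
#' @param pos 1-based position of `ref` within `refseq`'s coordinate system.
#' @param ref,alt allele strings (non-empty).
#' @param refseq the reference contig (character scalar) in whose coordinates
#'   `pos` is expressed.
#' @return list(pos, ref, alt), left-aligned, both alleles non-empty.
#' @export
leftNormalize <- function(pos, ref, alt, refseq) {
  stopifnot(nchar(ref) > 0L, nchar(alt) > 0L, ref != alt)
  ## canonical normalization: truncate shared rightmost bases, extending to
  ## the left with reference context whenever an allele would become empty,
  ## then trim shared leading bases
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      nr <- nr - 1L; na <- na - 1L
    } else if (nr > 0L && na > 0L) {
      break
    }
    if (nr == 0L || na == 0L) {
      if (pos <= 1L) {       # contig start: re-anchor on the right instead
        nxt <- substr(refseq, pos + max(nr, na), pos + max(nr, na))
        ref <- paste0(ref, nxt); alt <- paste0(alt, nxt)
        break
      }
      prev <- substr(refseq, pos - 1L, pos - 1L)
      ref <- paste0(prev, ref)
      alt <- paste0(prev, alt)
      pos <- pos - 1L
    }
  }
  ## trim shared leading bases (keep alleles non-empty)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Extract variants from a generated haplotype
#'
#' Aligns a haplotype sequence to a reference slice with [swAlign()] and
#' converts mismatches to SNVs and gaps to VCF-style anchored indels, each
#' left-normalized against the slice. Each variant carries the minimum
#' probability of the 4-mer token(s) that generated its bases and its offset
#' within the window.
#'
#' @param hap generated haplotype sequence (character scalar).
#' @param refslice reference slice the haplotype is aligned to (character).
#' @param sliceStart 1-based genomic position of the first base of `refslice`.
#' @param tokenProbs per-token probabilities from decoding (length
#'   `ceiling(nchar(hap)/4)`); defaults to 1.
#' @param minScore alignment score floor; below it the haplotype is treated as
#'   unalignable and an empty set is returned with a warning.
#' @return data.frame with columns pos (1-based genomic), ref, alt, kmer_prob,
#'   offset (0-based position of the variant within the slice).
#' @examples
#' extractVariants("ACGAACGTAC", "ACGTACGTAC", sliceStart = 1)
#' @export
extractVariants <- function(hap, refslice, sliceStart = 1L,
                            tokenProbs = NULL, minScore = -Inf) {
  empty <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), kmer_prob = numeric(0),
                      offset = integer(0), stringsAsFactors = FALSE)
  if (nchar(hap) == 0L) return(empty)
  if (is.null(tokenProbs)) tokenProbs <- rep(1, ceiling(nchar(hap) / 4))
  al <- swAlign(hap, refslice)
  if (al$score < minScore) {
    warning("haplotype alignment score ", al$score,
            " below floor; window skipped")
    return(empty)
  }
  co <- .cigar_ops(al$cigar)
  qpos <- 1L                       # 1-based position in hap
  spos <- al$subject_start         # 1-based position in refslice
  out <- list()
  tok_of <- function(q) tokenProbs[pmin(((q - 1L) %/% 4L) + 1L,
                                        length(tokenProbs))]
  for (k in seq_along(co$op)) {
    len <- co$len[k]; op <- co$op[k]
    if (op == "M") {
      qb <- substring(hap, qpos, qpos + len - 1L)
      sb <- substring(refslice, spos, spos + len - 1L)
      if (qb != sb) {
        qv <- strsplit(qb, "")[[1L]]
        sv <- strsplit(sb, "")[[1L]]
        mm <- which(qv != sv)
        for (i in mm) {
          out[[length(out) + 1L]] <- list(
            pos = spos + i - 1L, ref = sv[i], alt = qv[i],
            kmer_prob = min(tok_of(qpos + i - 1L)))
        }
      }
      qpos <- qpos + len; spos <- spos + len
    } else if (op == "I") {
      if (spos > 1L) {
        anchor <- spos - 1L
        ins <- substring(hap, qpos, qpos + len - 1L)
        ab <- substr(refslice, anchor, anchor)
        out[[length(out) + 1L]] <- list(
          pos = anchor, ref = ab, alt = paste0(ab, ins),
          kmer_prob = min(tok_of(qpos:(qpos + len - 1L))))
      }  # insertion before the slice start has no anchor; drop
      qpos <- qpos + len
    } else if (op == "D") {
      if (spos > 1L) {
        anchor <- spos - 1L
        del <- substring(refslice, spos, spos + len - 1L)
        ab <- substr(refslice, anchor, anchor)
        out[[length(out) + 1L]] <- list(
          pos = anchor, ref = paste0(ab, del), alt = ab,
          kmer_prob = min(tok_of(max(1L, qpos - 1L):min(nchar(hap), qpos))))
      }
      spos <- spos + len
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, lapply(out, function(v) {
    nz <- leftNormalize(v$pos, v$ref, v$alt, refslice)
    data.frame(pos = nz$pos + sliceStart - 1L, ref = nz$ref, alt = nz$alt,
               kmer_prob = v$kmer_prob, offset = nz$pos - 1L,
               stringsAsFactors = FALSE)
  }))
  ## merge duplicate records that normalize to the same variant
  key <- paste(res$pos, res$ref, res$alt)
  if (anyDuplicated(key)) {
    res <- do.call(rbind, lapply(split(res, key), function(d) {
      d$kmer_prob[1L] <- min(d$kmer_prob)
      d[1L, ]
    }))
  }
  rownames(res) <- NULL
  res[order(res$pos, res$ref, res$alt), , drop = FALSE]
}
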
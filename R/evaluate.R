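## genotype equivalence key: unordered alleles ("0|1" == "1|0" == "0/1")
.gt_key <- function(gt) {
  vapply(strsplit(gt, "[/|]"), function(a)
    paste(sort(a), collapse = "/"), character(1))
}

## classify each call and each truth record by exact normalized matching
.match_status <- function(calls, truth) {
  ckey <- if (nrow(calls)) paste(calls$chrom, calls$pos, calls$ref,
                                 calls$alt, sep = "\r") else character(0)
  tkey <- if (nrow(truth)) paste(truth$chrom, truth$pos, truth$ref,
                                 truth$alt, sep = "\r") else character(0)
  cgt <- if (nrow(calls)) .gt_key(calls$gt) else character(0)
  tgt <- if (nrow(truth)) .gt_key(truth$gt) else character(0)
  call_status <- rep("fp", length(ckey))
  truth_status <- rep("fn", length(tkey))
  m <- match(ckey, tkey)
  hit <- !is.na(m)
  gt_ok <- hit & cgt == tgt[ifelse(is.na(m), 1L, m)]
  call_status[gt_ok] <- "tp"
  call_status[hit & !gt_ok] <- "gt_mismatch"
  truth_status[m[gt_ok]] <- "tp"
  truth_status[m[hit & !gt_ok]] <- "gt_mismatch"
  list(call_status = call_status, truth_status = truth_status)
}

.variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "snv",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

.size_bin <- function(ref, alt) {
  d <- abs(nchar(alt) - nchar(ref))
  ifelse(d == 0L, "snv",
         ifelse(d <= 5L, "1-5", ifelse(d <= 15L, "6-15", ">15")))
}

#' Match calls against a truth set and summarize accuracy
#'
#' Exact matching of normalized records: a true positive requires identical
#' (chrom, pos, ref, alt) and an equivalent genotype (allele order and phase
#' are ignored). A call matching the allele but not the genotype is tallied as
#' a genotype mismatch, separately from TP (it counts as FP for the call and
#' FN for the truth record in the strict totals). Summaries are reported per
#' variant class (SNV, insertion, deletion) and per indel size bin (1-5, 6-15,
#' >15).
#'
#' @param calls,truth data.frames with chrom, pos, ref, alt, gt. `calls` may
#'   carry `qual`; no filtering is applied here.
#' @param confidentBed optional `GRanges`; both sets restricted to it.
#' @param reference optional reference for re-normalization of unnormalized
#'   input (applied with a warning).
#' @return list with `overall` (one-row data.frame: tp, fp, fn,
#'   genotype_mismatch, sensitivity, precision, f1), `by_class` and
#'   `by_size` data.frames.
#' @export
matchCalls <- function(calls, truth, confidentBed = NULL, reference = NULL) {
  restrict <- function(df) {
    if (is.null(confidentBed) || nrow(df) == 0L) return(df)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
    df[IRanges::overlapsAny(gr, confidentBed), , drop = FALSE]
  }
  renorm <- function(df) {
    if (is.null(reference) || nrow(df) == 0L) return(df)
    for (i in seq_len(nrow(df))) {
      refseq <- .get_ref(reference, df$chrom[i], 1L,
                         df$pos[i] + nchar(df$ref[i]) + 1L)
      nz <- leftNormalize(df$pos[i], df$ref[i], df$alt[i], refseq)
      if (nz$pos != df$pos[i] || nz$ref != df$ref[i] || nz$alt != df$alt[i]) {
        warning("unnormalized record at ", df$chrom[i], ":", df$pos[i],
                "; normalized internally")
        df$pos[i] <- nz$pos; df$ref[i] <- nz$ref; df$alt[i] <- nz$alt
      }
    }
    df
  }
  calls <- renorm(restrict(calls))
  truth <- renorm(restrict(truth))
  st <- .match_status(calls, truth)
  summarize <- function(cs, ts) {
    tp <- sum(cs == "tp"); gm <- sum(cs == "gt_mismatch")
    fp <- sum(cs != "tp")                  # includes genotype mismatches
    fn <- sum(ts != "tp")
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(sens) && !is.na(prec) && sens + prec > 0)
      2 * sens * prec / (sens + prec) else NA_real_
    data.frame(tp = tp, fp = fp, fn = fn, genotype_mismatch = gm,
               sensitivity = sens, precision = prec, f1 = f1)
  }
  overall <- summarize(st$call_status, st$truth_status)
  cclass <- if (nrow(calls)) .variant_class(calls$ref, calls$alt) else character(0)
  tclass <- if (nrow(truth)) .variant_class(truth$ref, truth$alt) else character(0)
  by_class <- do.call(rbind, lapply(c("snv", "insertion", "deletion"),
    function(cl) cbind(class = cl,
                       summarize(st$call_status[cclass == cl],
                                 st$truth_status[tclass == cl]))))
  csize <- if (nrow(calls)) .size_bin(calls$ref, calls$alt) else character(0)
  tsize <- if (nrow(truth)) .size_bin(truth$ref, truth$alt) else character(0)
  by_size <- do.call(rbind, lapply(c("1-5", "6-15", ">15"),
    function(b) cbind(size_bin = b,
                      summarize(st$call_status[csize == b],
                                st$truth_status[tsize == b]))))
  list(overall = overall, by_class = by_class, by_size = by_size)
}

#' Phase precision as a percentage
#'
#' The phase-precision statistic for one distance bin:
#' `100 * correct / (correct + incorrect)`.
#'
#' @param correct,incorrect non-negative pair counts.
#' @return precision in percent, `NA` when the bin is empty.
#' @examples
#' phasePrecisionPercent(12726, 315)   # 97.6
#' @export
phasePrecisionPercent <- function(correct, incorrect) {
  stopifnot(all(correct >= 0), all(incorrect >= 0))
  ifelse(correct + incorrect == 0, NA_real_,
         100 * correct / (correct + incorrect))
}

#' Distance-binned phase precision against a phased truth set
#'
#' For each adjacent pair of variants in the same call phase set, the relative
#' phase (cis when both genotypes have the same orientation, trans otherwise)
#' is compared to the truth sample's phasing. Pairs are binned by the distance
#' between the two POS values (1-24, 25-49, 50-100, >100 bp). Calls below
#' `minQual` are discarded first, as are pairs where the truth provides no
#' phase or where a genotype conflicts with the truth. Bins with no retained
#' pairs are omitted.
#'
#' @param calls call data.frame with chrom, pos, ref, alt, gt, ps (and
#'   optionally qual).
#' @param truth truth data.frame with phased gt (`|`).
#' @param minQual phred filter applied to `calls$qual` when present.
#' @return data.frame with bin, correct, incorrect, precision (percent).
#' @export
phasePrecision <- function(calls, truth, minQual = 10) {
  if (nrow(calls) && "qual" %in% colnames(calls) && !all(is.na(calls$qual)))
    calls <- calls[!is.na(calls$qual) & calls$qual >= minQual, , drop = FALSE]
  calls <- calls[!is.na(calls$ps) & calls$gt %in% c("0|1", "1|0"), ,
                 drop = FALSE]
  bins <- c("1-24", "25-49", "50-100", ">100")
  tally <- stats::setNames(rep(0L, length(bins)), bins)
  wrong <- tally
  if (nrow(calls)) {
    tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = "\r")
    for (grp in split(seq_len(nrow(calls)),
                      paste(calls$chrom, calls$ps))) {
      if (length(grp) < 2L) next
      grp <- grp[order(calls$pos[grp])]
      for (k in seq_len(length(grp) - 1L)) {
        i <- grp[k]; j <- grp[k + 1L]
        ti <- match(paste(calls$chrom[i], calls$pos[i], calls$ref[i],
                          calls$alt[i], sep = "\r"), tkey)
        tj <- match(paste(calls$chrom[j], calls$pos[j], calls$ref[j],
                          calls$alt[j], sep = "\r"), tkey)
        if (is.na(ti) || is.na(tj)) next
        tgi <- truth$gt[ti]; tgj <- truth$gt[tj]
        ## truth must provide phase and agree on the genotype class
        if (!tgi %in% c("0|1", "1|0") || !tgj %in% c("0|1", "1|0")) next
        call_cis <- calls$gt[i] == calls$gt[j]
        truth_cis <- tgi == tgj
        d <- abs(calls$pos[j] - calls$pos[i])
        bin <- if (d <= 24) "1-24" else if (d <= 49) "25-49"
          else if (d <= 100) "50-100" else ">100"
        if (call_cis == truth_cis) tally[bin] <- tally[bin] + 1L
        else wrong[bin] <- wrong[bin] + 1L
      }
    }
  }
  keep <- tally + wrong > 0L
  data.frame(bin = bins[keep], correct = as.integer(tally[keep]),
             incorrect = as.integer(wrong[keep]),
             precision = phasePrecisionPercent(tally[keep], wrong[keep]),
             stringsAsFactors = FALSE)
}
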
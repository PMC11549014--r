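#' Smith-Waterman alignment of a query against a reference slice
#'
#' Affine-gap alignment that is global in the query (every query base is
#' accounted for, so terminal indels are never silently clipped) and local in
#' the subject. This is the aligner used both for extracting variants from
#' generated haplotypes and for read-backed phase resolution. Default scoring:
#' match +2, mismatch -4, gap open -6, gap extend -1 (a gap of length k costs
#' `6 + k`).
#'
#' @param query,subject character scalars (A/C/G/T/N).
#' @param match,mismatch substitution scores.
#' @param gapOpen,gapExtend positive gap penalties.
#' @return list with `score`, `cigar` (M/I/D in subject coordinates, I =
#'   insertion relative to the subject), `subject_start` and `subject_end`
#'   (1-based positions of the first/last consumed subject base).
#' @examples
#' swAlign("ACGAACGTAC", "ACGTACGTAC")$cigar
#' @export
swAlign <- function(query, subject, match = 2, mismatch = -4,
                    gapOpen = 6, gapExtend = 1) {
  stopifnot(is.character(query), is.character(subject),
            length(query) == 1L, length(subject) == 1L)
  .sw_align_cpp(query, subject, match, mismatch, gapOpen, gapExtend)
}

## parse a cigar string into integer lengths + character ops
.cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*")
    return(list(len = integer(0), op = character(0)))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  stopifnot(length(len) == length(op))
  list(len = len, op = op)
}

.cigar_ref_width <- function(cigar) {
  co <- .cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "D", "N", "=", "X")])
}

.cigar_string <- function(len, op) {
  if (length(len) == 0L) return("*")
  ## merge adjacent identical ops
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (length(len) == 0L) return("*")
  j <- 1L
  for (i in seq_along(op)[-1L]) {
    if (op[i] == op[j]) len[j] <- len[j] + len[i]
    else { j <- j + 1L; len[j] <- len[i]; op[j] <- op[i] }
  }
  paste0(len[seq_len(j)], op[seq_len(j)], collapse = "")
}
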
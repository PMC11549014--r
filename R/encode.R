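#' @importFrom Rsamtools FaFile scanFa ScanBamParam scanBam scanBamFlag
NULL

## run expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic per-window seed derived from the global seed
.window_seed <- function(seed, chrom, start) {
  (as.integer(seed) %% 100003L) * 20011L +
    (as.integer(start) %% 65011L) * 17L +
    sum(utf8ToInt(as.character(chrom))) %% 1009L
}

## fetch reference sequence; `reference` is a named character vector of
## contigs, an Rsamtools::FaFile, or a path to an indexed FASTA.
## Returns the available sequence (may be shorter than requested at contig
## ends); `start` must be >= 1.
.get_ref <- function(reference, chrom, start, end) {
  stopifnot(start >= 1L)
  if (is.character(reference) && !is.null(names(reference))) {
    if (!chrom %in% names(reference))
      stop("contig not found in reference: ", chrom)
    contig <- reference[[chrom]]
    if (start > nchar(contig)) return("")
    return(toupper(substr(contig, start, min(end, nchar(contig)))))
  }
  fa <- if (is(reference, "FaFile")) reference else Rsamtools::FaFile(reference)
  info <- Rsamtools::seqinfo(fa)
  if (!chrom %in% GenomeInfoDb::seqnames(info))
    stop("contig not found in reference: ", chrom)
  len <- GenomeInfoDb::seqlengths(info)[[chrom]]
  if (start > len) return("")
  rng <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, min(end, len)))
  toupper(as.character(Rsamtools::scanFa(fa, rng)[[1L]]))
}

## load reads overlapping a window from a BAM file or an in-memory read table
## (data.frame with qname, chrom, pos, cigar, seq, qual, strand, mapq).
.load_reads <- function(source, window) {
  chrom <- as.character(seqnames(window))
  if (is.data.frame(source)) {
    r <- source[source$chrom == chrom, , drop = FALSE]
    if (nrow(r) == 0L) return(r)
    rend <- if ("rend" %in% colnames(r)) r$rend else
      r$pos + vapply(r$cigar, .cigar_ref_width, integer(1),
                     USE.NAMES = FALSE) - 1L
    keep <- r$pos <= end(window) & rend >= start(window)
    return(r[keep, , drop = FALSE])
  }
  bf <- if (is(source, "BamFile")) source else Rsamtools::BamFile(source)
  if (is.na(Rsamtools::index(bf)) || !file.exists(Rsamtools::index(bf)))
    stop("alignment source is not indexed: ", Rsamtools::path(bf))
  hdr <- Rsamtools::scanBamHeader(bf)
  if (!chrom %in% names(hdr$targets))
    stop("contig not found in alignment source: ", chrom)
  param <- Rsamtools::ScanBamParam(
    which = window,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    what = c("qname", "pos", "cigar", "seq", "qual", "strand", "mapq"))
  x <- Rsamtools::scanBam(bf, param = param)[[1L]]
  data.frame(qname = x$qname, chrom = chrom, pos = x$pos, cigar = x$cigar,
             seq = as.character(x$seq),
             qual = as.character(x$qual),
             strand = as.character(x$strand),
             mapq = ifelse(is.na(x$mapq), 0L, x$mapq),
             stringsAsFactors = FALSE)
}

#' Fetch, sort and downsample the reads overlapping a window
#'
#' Reads are sorted by the reference coordinate of their first aligned base
#' (ties broken by read name, so the order is identical for any source).
#' If more than `maxReads - 1` reads overlap the window they are uniformly
#' downsampled (the reference sequence occupies the first of the `maxReads`
#' rows), preserving sort order; the subsample is seeded per window so
#' repeated calls are reproducible. Reads with mapping quality 0 are retained.
#'
#' @param source indexed BAM/CRAM path (or `BamFile`), or an in-memory read
#'   table (`data.frame` with columns qname, chrom, pos, cigar, seq, qual,
#'   strand, mapq).
#' @param window a length-1 `GRanges`.
#' @param maxReads row budget `r` of the encoded region (default 150).
#' @param seed global seed combined with the window coordinates to seed the
#'   downsampling RNG.
#' @return the read table, sorted, with at most `maxReads - 1` rows.
#' @export
extractReads <- function(source, window, maxReads = 150L, seed = 0L) {
  r <- .load_reads(source, window)
  if (nrow(r) == 0L) return(r)
  r <- r[order(r$pos, r$qname), , drop = FALSE]   # qname breaks ties

  cap <- maxReads - 1L
  if (nrow(r) > cap) {
    keep <- .with_seed(.window_seed(seed, seqnames(window), start(window)),
                       sort(sample.int(nrow(r), cap)))
    r <- r[keep, , drop = FALSE]
  }
  rownames(r) <- NULL
  r
}

#' Per-base feature vector
#'
#' The ten features encoded for every (position, read) cell: one-hot base
#' (A,C,G,T), base quality / 100, a consumes-reference flag (0 for insertion
#' bases), a consumes-read flag (0 for deletions), reverse-strand flag,
#' clipped-read flag, and mapping quality / 100. An aligned or insertion base
#' of `N` encodes as an all-zero one-hot with its flags set.
#'
#' @param base base character (ignored for deletions).
#' @param qual integer base quality (phred).
#' @param type `"aligned"`, `"deletion"` or `"insertion"`.
#' @param reverseStrand,clipped logical flags for the read.
#' @param mapq integer mapping quality.
#' @return numeric vector of length 10.
#' @examples
#' baseFeatures("C", 30, "aligned", FALSE, FALSE, 60)
#' @export
baseFeatures <- function(base = "N", qual = 0, type = c("aligned", "deletion",
                                                        "insertion"),
                         reverseStrand = FALSE, clipped = FALSE, mapq = 60) {
  type <- match.arg(type)
  v <- numeric(10)
  if (type != "deletion") {
    code <- .base_codes(toupper(base))
    if (is.na(code)) {
      if (toupper(base) != "N")
        stop("cannot encode base '", base, "'")
    } else v[code + 1L] <- 1
    v[5L] <- qual / 100
    v[7L] <- 1                                   # consumes read
    v[6L] <- if (type == "aligned") 1 else 0     # consumes reference
  } else {
    v[6L] <- 1
  }
  v[8L] <- as.numeric(reverseStrand)
  v[9L] <- as.numeric(clipped)
  v[10L] <- mapq / 100
  v
}

## CIGAR walk for one read: per window column, the encoded event.
## Returns list(cols, feat) where cols are 1-based window columns and feat is
## an [n, 10] matrix. An insertion replaces the event of the column it
## follows, encoding the first inserted base with consumes_reference = 0.
.read_events <- function(pos, cigar, seq, qual, strand, mapq,
                         win_start, win_end) {
  co <- .cigar_ops(cigar)
  clipped <- any(co$op %in% c("S", "H"))
  rev <- identical(strand, "-")
  qn <- as.integer(charToRaw(qual)) - 33L
  sv <- .base_codes(seq)                  # NA for N
  refp <- pos
  readp <- 1L
  n_ref <- .cigar_ref_width(cigar)
  cols <- integer(0); code <- integer(0); q <- numeric(0)
  cr <- numeric(0); cq <- numeric(0)
  ins <- list()
  for (k in seq_along(co$op)) {
    len <- co$len[k]; op <- co$op[k]
    if (op %in% c("M", "=", "X")) {
      idx <- refp:(refp + len - 1L)
      cols <- c(cols, idx)
      code <- c(code, sv[readp:(readp + len - 1L)])
      q <- c(q, qn[readp:(readp + len - 1L)])
      cr <- c(cr, rep(1, len)); cq <- c(cq, rep(1, len))
      refp <- refp + len; readp <- readp + len
    } else if (op %in% c("D", "N")) {
      idx <- refp:(refp + len - 1L)
      cols <- c(cols, idx)
      code <- c(code, rep(NA_integer_, len))
      q <- c(q, rep(0, len))
      cr <- c(cr, rep(1, len)); cq <- c(cq, rep(0, len))
      refp <- refp + len
    } else if (op == "I") {
      if (refp > pos)        # leading insertions have no anchor column
        ins[[length(ins) + 1L]] <- list(col = refp - 1L,
                                        code = sv[readp], q = qn[readp])
      readp <- readp + len
    } else if (op == "S") {
      readp <- readp + len
    }                         # H consumes nothing
  }
  ## insertion overrides: encode first inserted base at the preceding column
  for (iv in ins) {
    at <- which(cols == iv$col)
    if (length(at)) {
      at <- at[1L]
      code[at] <- iv$code; q[at] <- iv$q
      cr[at] <- 0; cq[at] <- 1
    }
  }
  keep <- cols >= win_start & cols <= win_end
  if (!any(keep)) return(NULL)
  cols <- cols[keep]; code <- code[keep]; q <- q[keep]
  cr <- cr[keep]; cq <- cq[keep]
  n <- length(cols)
  feat <- matrix(0, n, 10L)
  hot <- !is.na(code)
  feat[cbind(which(hot), code[hot] + 1L)] <- 1
  feat[, 5L] <- ifelse(cq > 0, q / 100, 0)
  feat[, 6L] <- cr
  feat[, 7L] <- cq
  feat[, 8L] <- as.numeric(rev)
  feat[, 9L] <- as.numeric(clipped)
  feat[, 10L] <- mapq / 100
  list(cols = cols - win_start + 1L, feat = feat)
}

#' Encode a genomic window as a model input tensor
#'
#' Builds the `[g, r, 10]` array the model consumes: row 1 of the read axis is
#' the reference sequence (base quality feature 1.0, all flags 0); rows
#' 2..(k+1) are the reads returned by [extractReads()], in sorted order; any
#' remaining rows (and any cell without an aligned base) are zero. Windows
#' extending past the contig end are clipped and zero-padded with a warning.
#'
#' @inheritParams extractReads
#' @param reference named character vector of contigs, `FaFile`, or indexed
#'   FASTA path.
#' @param windowSize window width `g` (default 150); `window` must have this
#'   width.
#' @return an [EncodedRegion-class].
#' @export
encodeRegion <- function(source, reference, window, maxReads = 150L,
                         seed = 0L, windowSize = 150L) {
  stopifnot(is(window, "GRanges"), length(window) == 1L)
  if (width(window) != windowSize)
    stop("window width ", width(window), " != configured size ", windowSize)
  if (start(window) < 1L) stop("window start must be >= 1")
  g <- windowSize
  chrom <- as.character(seqnames(window))
  refseq <- .get_ref(reference, chrom, start(window), end(window))
  if (nchar(refseq) < g)
    warning("window extends past end of contig ", chrom,
            "; clipped and zero-padded")
  arr <- array(0, dim = c(g, as.integer(maxReads), 10L))
  ## reference row
  if (nchar(refseq) > 0L) {
    rc <- .base_codes(refseq)
    idx <- which(!is.na(rc))
    arr[cbind(idx, 1L, rc[idx] + 1L)] <- 1
    arr[seq_len(nchar(refseq)), 1L, 5L] <- 1      # quality 100 / 100
  }
  reads <- extractReads(source, window, maxReads = maxReads, seed = seed)
  if (nrow(reads)) {
    for (i in seq_len(nrow(reads))) {
      ev <- .read_events(reads$pos[i], reads$cigar[i], reads$seq[i],
                         reads$qual[i], reads$strand[i], reads$mapq[i],
                         start(window), end(window))
      if (is.null(ev)) next
      row <- i + 1L
      for (f in 1:10)
        arr[cbind(ev$cols, row, f)] <- ev$feat[, f]
    }
  }
  new("EncodedRegion", window = window, array = arr,
      readIds = if (nrow(reads)) as.character(reads$qname) else character(0))
}

## pack an encoded array into raw bytes (features are multiples of 1/100 in
## [0,1], so value*100 fits one byte); used to hold training sets compactly
.pack_region <- function(arr) {
  list(dim = dim(arr), bytes = as.raw(round(arr * 100)))
}

.unpack_region <- function(p) {
  array(as.integer(p$bytes) / 100, dim = p$dim)
}
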
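## Independent oracles used to check the implementation against brute force.
## These deliberately re-derive the same quantities through different code
## paths (plain R dynamic programming, exhaustive enumeration) and share no
## internals with the package functions they validate.

## --- independent CIGAR interpreter -----------------------------------------
## returns the sorted 1-based window columns where a read has any encoded
## event (aligned base, deletion, or insertion anchor)
oracle_read_columns <- function(pos, cigar, win_start, win_end) {
  nums <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  refp <- pos
  cols <- integer(0)
  for (k in seq_along(ops)) {
    len <- nums[k]; op <- ops[k]
    if (op %in% c("M", "=", "X", "D", "N")) {
      cols <- c(cols, refp:(refp + len - 1L))
      refp <- refp + len
    } else if (op == "I" && refp > pos) {
      cols <- c(cols, refp - 1L)          # insertion anchors one column left
    }
  }
  sort(unique(cols[cols >= win_start & cols <= win_end])) - win_start + 1L
}

## --- brute-force glocal affine aligner --------------------------------------
## plain R dynamic programme over three states with the same scoring
## convention (gap of length k costs open + k*ext), written independently of
## the C++ kernel; returns score and the alignment ops
oracle_align <- function(q, s, match = 2, mismatch = -4, open = 6, ext = 1) {
  qv <- strsplit(q, "")[[1L]]; sv <- strsplit(s, "")[[1L]]
  m <- length(qv); n <- length(sv)
  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1); Iq <- M; Is <- M
  M[1, ] <- 0
  for (i in seq_len(m)) Iq[i + 1, 1] <- -(open + i * ext)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sc <- if (qv[i] == sv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], Is[i, j], Iq[i, j]) + sc
      Is[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Is[i + 1, j] - ext,
                              Iq[i + 1, j] - open - ext)
      Iq[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Is[i, j + 1] - open - ext, Iq[i, j + 1] - ext)
    }
  }
  final <- pmax(M[m + 1, ], Iq[m + 1, ])
  score <- max(final)
  ## traceback (prefer M, then Is, then Iq, end at the smallest j)
  j <- which(final == score)[1L] - 1L
  st <- if (M[m + 1, j + 1] >= Iq[m + 1, j + 1]) "M" else "Iq"
  i <- m
  ops <- character(0)
  while (i > 0) {
    if (st == "M") {
      sc <- if (qv[i] == sv[j]) match else mismatch
      prev <- c(M[i, j], Is[i, j], Iq[i, j])
      from <- c("M", "Is", "Iq")[which.max(prev)]
      ops <- c("M", ops); i <- i - 1L; j <- j - 1L
      st <- from
    } else if (st == "Is") {
      cand <- c(M[i + 1, j] - open - ext, Is[i + 1, j] - ext,
                Iq[i + 1, j] - open - ext)
      from <- c("M", "Is", "Iq")[which.max(cand)]
      ops <- c("D", ops); j <- j - 1L
      st <- from
    } else {
      cand <- c(M[i, j + 1] - open - ext, Is[i, j + 1] - open - ext,
                Iq[i, j + 1] - ext)
      from <- c("M", "Is", "Iq")[which.max(cand)]
      ops <- c("I", ops); i <- i - 1L
      st <- from
    }
  }
  list(score = score, ops = ops, subject_start = j + 1L)
}

## textbook left-alignment of a single variant record, working on base
## vectors: strip equal rightmost bases (borrowing reference context leftward
## when an allele empties), then strip equal leading bases
oracle_normalize <- function(pos, ref, alt, refseq) {
  rv <- strsplit(ref, "")[[1]]
  av <- strsplit(alt, "")[[1]]
  rseq <- strsplit(refseq, "")[[1]]
  repeat {
    if (length(rv) && length(av) && rv[length(rv)] == av[length(av)]) {
      rv <- rv[-length(rv)]; av <- av[-length(av)]
    } else if (length(rv) && length(av)) break
    if (!length(rv) || !length(av)) {
      if (pos <= 1) {
        nxt <- rseq[pos + max(length(rv), length(av))]
        rv <- c(rv, nxt); av <- c(av, nxt)
        break
      }
      rv <- c(rseq[pos - 1], rv)
      av <- c(rseq[pos - 1], av)
      pos <- pos - 1
    }
  }
  while (length(rv) > 1 && length(av) > 1 && rv[1] == av[1]) {
    rv <- rv[-1]; av <- av[-1]; pos <- pos + 1
  }
  paste(pos, paste(rv, collapse = ""), paste(av, collapse = ""))
}

## brute-force variant extraction: oracle alignment + diff + normalization
oracle_variants <- function(hap, refseq) {
  al <- oracle_align(hap, refseq)
  qpos <- 1L; spos <- al$subject_start
  out <- character(0)
  k <- 1L
  ops <- al$ops
  while (k <= length(ops)) {
    op <- ops[k]
    len <- 0L
    while (k <= length(ops) && ops[k] == op) { len <- len + 1L; k <- k + 1L }
    if (op == "M") {
      for (t in seq_len(len)) {
        qb <- substr(hap, qpos + t - 1L, qpos + t - 1L)
        sb <- substr(refseq, spos + t - 1L, spos + t - 1L)
        if (qb != sb)
          out <- c(out, paste(spos + t - 1L, sb, qb))
      }
      qpos <- qpos + len; spos <- spos + len
    } else if (op == "I") {
      if (spos > 1L) {
        anchor <- substr(refseq, spos - 1L, spos - 1L)
        ins <- substr(hap, qpos, qpos + len - 1L)
        out <- c(out, oracle_normalize(spos - 1L, anchor,
                                       paste0(anchor, ins), refseq))
      }
      qpos <- qpos + len
    } else {
      if (spos > 1L) {
        anchor <- substr(refseq, spos - 1L, spos - 1L)
        del <- substr(refseq, spos, spos + len - 1L)
        out <- c(out, oracle_normalize(spos - 1L, paste0(anchor, del),
                                       anchor, refseq))
      }
      spos <- spos + len
    }
  }
  sort(unique(out))
}

## exhaustive genotype vote tally
oracle_vote <- function(gts) {
  het <- sum(gts %in% c("het0", "het1"))
  hom <- sum(gts == "hom")
  if (het >= hom) "het" else "hom"
}

## all sequences within edit distance <= 2 of `s` over ACGT
edit_neighborhood2 <- function(s) {
  bases <- c("A", "C", "G", "T")
  one <- function(x) {
    n <- nchar(x)
    xv <- strsplit(x, "")[[1L]]
    out <- character(0)
    for (i in seq_len(n)) {
      for (b in bases[bases != xv[i]])       # substitution
        out <- c(out, paste0(substr(x, 1, i - 1), b, substr(x, i + 1, n)))
      out <- c(out, paste0(substr(x, 1, i - 1), substr(x, i + 1, n)))  # del
    }
    for (i in 0:n)                            # insertions
      for (b in bases)
        out <- c(out, paste0(substr(x, 1, i), b, substr(x, i + 1, n)))
    unique(out)
  }
  n1 <- one(s)
  unique(c(s, n1, unlist(lapply(n1, one))))
}
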
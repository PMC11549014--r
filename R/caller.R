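## per-position mismatch/indel support over a span, from the CIGAR walks of
## all overlapping reads; used for candidate-region detection and the
## depth / alt-support call features
.pileup_events <- function(reads, refseq, span_start, span_end) {
  n <- span_end - span_start + 1L
  diffc <- integer(n)        # reads differing from the reference (mm or indel)
  depth <- integer(n)
  rcodes <- .base_codes(substr(refseq, span_start, span_end))
  alt_events <- list()       # per read: data.frame(col, kind, base)
  for (i in seq_len(nrow(reads))) {
    ev <- .read_events(reads$pos[i], reads$cigar[i], reads$seq[i],
                       reads$qual[i], reads$strand[i], reads$mapq[i],
                       span_start, span_end)
    if (is.null(ev)) next
    depth[ev$cols] <- depth[ev$cols] + 1L
    code <- max.col(ev$feat[, 1:4, drop = FALSE]) - 1L
    code[rowSums(ev$feat[, 1:4, drop = FALSE]) == 0] <- NA_integer_
    cr <- ev$feat[, 6L]; cq <- ev$feat[, 7L]
    is_del <- cr == 1 & cq == 0
    is_ins <- cr == 0
    is_mm <- cr == 1 & cq == 1 & !is.na(code) & code != rcodes[ev$cols]
    hit <- is_del | is_ins | is_mm
    diffc[ev$cols[hit]] <- diffc[ev$cols[hit]] + 1L
    kind <- ifelse(is_del, "del", ifelse(is_ins, "ins",
                                         ifelse(is_mm, "mm", "ref")))
    alt_events[[i]] <- data.frame(col = ev$cols, kind = kind, code = code,
                                  stringsAsFactors = FALSE)
  }
  list(diff = diffc, depth = depth, events = alt_events)
}

#' Find candidate variant regions
#'
#' Flags every genomic position where at least `minSupport` reads carry a base
#' differing from the reference or an indel, pads each seed by `pad` bp in
#' both directions, and merges regions closer than `mergeDist` bp.
#'
#' @param source alignment source (BAM path/`BamFile` or read table).
#' @param reference reference (named character vector, `FaFile` or path).
#' @param span length-1 `GRanges` to scan.
#' @param minSupport minimum differing reads (default 3).
#' @param pad padding around each seed (default 4).
#' @param mergeDist regions closer than this are merged (default 100).
#' @return `GRanges` of candidate regions; metadata column `seeds` holds the
#'   flagged positions (comma-separated).
#' @export
findCandidateRegions <- function(source, reference, span, minSupport = 3L,
                                 pad = 4L, mergeDist = 100L) {
  stopifnot(is(span, "GRanges"), length(span) == 1L)
  chrom <- as.character(seqnames(span))
  refseq <- .get_ref(reference, chrom, 1L, end(span))
  reads <- .load_reads(source, span)
  empty <- GenomicRanges::GRanges()
  if (nrow(reads) == 0L) return(empty)
  pe <- .pileup_events(reads, refseq, start(span), end(span))
  seeds <- which(pe$diff >= minSupport) + start(span) - 1L
  if (length(seeds) == 0L) return(empty)
  lo <- pmax(1L, seeds - pad)
  hi <- pmin(nchar(refseq), seeds + pad)
  ## merge padded seed intervals closer than mergeDist
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]; sd <- seeds[o]
  rs <- lo[1L]; re <- hi[1L]; rseeds <- sd[1L]
  out <- list()
  flush <- function() out[[length(out) + 1L]] <<-
    list(start = rs, end = re, seeds = rseeds)
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] - re < mergeDist) {
      re <- max(re, hi[i]); rseeds <- c(rseeds, sd[i])
    } else {
      flush()
      rs <- lo[i]; re <- hi[i]; rseeds <- sd[i]
    }
  }
  flush()
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    vapply(out, `[[`, numeric(1), "start"),
    vapply(out, `[[`, numeric(1), "end")))
  S4Vectors::mcols(gr)$seeds <- vapply(out, function(x)
    paste(x$seeds, collapse = ","), character(1))
  gr
}

#' Plan decoding windows for a candidate region
#'
#' Windows begin `upstream` bases before the first flagged position and
#' advance by `stepSize` until a window start passes the last flagged
#' position; all windows have width `windowSize` and starts are clamped to the
#' contig.
#'
#' @param region a length-1 `GRanges` with a `seeds` metadata column (from
#'   [findCandidateRegions()]), or a plain region whose start/end act as
#'   first/last seed.
#' @param stepSize window step `k` (default 25).
#' @param upstream bases before the first seed (default 100).
#' @param windowSize window width (default 150).
#' @return `GRanges` of windows.
#' @export
planWindows <- function(region, stepSize = 25L, upstream = 100L,
                        windowSize = 150L) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  seeds <- S4Vectors::mcols(region)$seeds
  if (!is.null(seeds) && !is.na(seeds) && nzchar(seeds))
    seeds <- as.integer(strsplit(seeds, ",")[[1L]])
  else seeds <- c(start(region), end(region))
  first <- min(seeds); last <- max(seeds)
  starts <- unique(pmax(1L, seq(first - upstream, last, by = stepSize)))
  GenomicRanges::GRanges(seqnames(region),
                         IRanges::IRanges(as.integer(starts),
                                          width = windowSize))
}

## decode one window and convert both generated haplotypes to window calls
.call_window <- function(model, source, reference, window, seed = 0L,
                         slack = 30L) {
  cfg <- model@config
  er <- encodeRegion(source, reference, window, maxReads = cfg@maxReads,
                     seed = seed, windowSize = cfg@windowSize)
  pred <- greedyDecode(model, er)
  chrom <- as.character(seqnames(window))
  slice_start <- max(1L, start(window) - slack)
  refslice <- .get_ref(reference, chrom, slice_start, end(window) + slack)
  v0 <- extractVariants(pred@hap0, refslice, slice_start, pred@tokenProbs0)
  v1 <- extractVariants(pred@hap1, refslice, slice_start, pred@tokenProbs1)
  keep0 <- v0$pos >= start(window) & v0$pos <= end(window)
  keep1 <- v1$pos >= start(window) & v1$pos <= end(window)
  v0 <- v0[keep0, , drop = FALSE]; v1 <- v1[keep1, , drop = FALSE]
  k0 <- paste(v0$pos, v0$ref, v0$alt)
  k1 <- paste(v1$pos, v1$ref, v1$alt)
  keys <- union(k0, k1)
  if (length(keys) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), kmer_prob = numeric(0),
                      pos_in_window = integer(0), win_start = integer(0)))
  rows <- lapply(keys, function(k) {
    in0 <- k %in% k0; in1 <- k %in% k1
    r <- if (in0) v0[match(k, k0), ] else v1[match(k, k1), ]
    kp <- min(c(if (in0) v0$kmer_prob[match(k, k0)],
                if (in1) v1$kmer_prob[match(k, k1)]))
    data.frame(chrom = chrom, pos = r$pos, ref = r$ref, alt = r$alt,
               gt = if (in0 && in1) "hom" else if (in0) "het0" else "het1",
               kmer_prob = kp, pos_in_window = r$pos - start(window),
               win_start = start(window), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Merge per-window calls by majority vote
#'
#' Calls are keyed by normalized (chrom, pos, ref, alt). The genotype is the
#' majority vote over the windows containing the call (heterozygous in two
#' windows and homozygous in one merges to heterozygous); ties break toward
#' heterozygous. Variants seen in only a minority of their covering windows
#' are retained — the vote counts feed the quality classifier, which is the
#' intended filter.
#'
#' @param windowCalls data.frame of per-window calls (rows from all windows of
#'   one candidate region).
#' @return data.frame with one row per distinct variant: chrom, pos, ref, alt,
#'   genotype (`het` / `hom`), vote counts, window_count, kmer summaries and
#'   window-position summary.
#' @export
mergeWindowCalls <- function(windowCalls) {
  if (nrow(windowCalls) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), votes_het = integer(0),
                      votes_hom = integer(0), window_count = integer(0),
                      kmer_min = numeric(0), kmer_mean = numeric(0),
                      pos_off_mean = numeric(0)))
  key <- paste(windowCalls$chrom, windowCalls$pos, windowCalls$ref,
               windowCalls$alt, sep = "\r")
  rows <- lapply(split(windowCalls, key), function(d) {
    het <- sum(d$gt %in% c("het0", "het1"))
    hom <- sum(d$gt == "hom")
    data.frame(chrom = d$chrom[1L], pos = d$pos[1L], ref = d$ref[1L],
               alt = d$alt[1L],
               genotype = if (het >= hom) "het" else "hom",
               votes_het = het, votes_hom = hom, window_count = nrow(d),
               kmer_min = min(d$kmer_prob), kmer_mean = mean(d$kmer_prob),
               pos_off_mean = mean(abs(d$pos_in_window - 75)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## cis/trans orientation of merged variant pairs from shared decoded windows,
## plus phase-set assignment by graph 2-coloring
.phase_annotate <- function(merged, windowCalls) {
  n <- nrow(merged)
  if (n == 0L) {
    merged$n_cis <- integer(0); merged$n_trans <- integer(0)
    merged$ps <- integer(0); merged$gt <- character(0)
    return(merged)
  }
  merged$n_cis <- 0L; merged$n_trans <- 0L
  merged$ps <- NA_integer_
  merged$gt <- ifelse(merged$genotype == "hom", "1/1", "0/1")
  mkey <- paste(merged$chrom, merged$pos, merged$ref, merged$alt, sep = "\r")
  wkey <- paste(windowCalls$chrom, windowCalls$pos, windowCalls$ref,
                windowCalls$alt, sep = "\r")
  widx <- match(wkey, mkey)
  ## orientation votes between pairs sharing a window
  cis_votes <- matrix(0L, n, n); trans_votes <- matrix(0L, n, n)
  for (w in split(seq_len(nrow(windowCalls)), windowCalls$win_start)) {
    if (length(w) < 2L) next
    for (a in seq_along(w)[-length(w)]) {
      for (b in (a + 1L):length(w)) {
        i <- widx[w[a]]; j <- widx[w[b]]
        ga <- windowCalls$gt[w[a]]; gb <- windowCalls$gt[w[b]]
        same <- ga == "hom" || gb == "hom" || ga == gb
        if (same) {
          cis_votes[i, j] <- cis_votes[i, j] + 1L
          cis_votes[j, i] <- cis_votes[i, j]
        } else {
          trans_votes[i, j] <- trans_votes[i, j] + 1L
          trans_votes[j, i] <- trans_votes[i, j]
        }
      }
    }
  }
  rel <- matrix(0L, n, n)      # 1 = cis, -1 = trans
  rel[cis_votes > trans_votes] <- 1L
  rel[trans_votes > cis_votes] <- -1L
  rel[cis_votes == trans_votes & cis_votes > 0L] <- 1L  # tie: cis
  for (i in seq_len(n)) {
    if (n > 1L) {
      merged$n_cis[i] <- sum(rel[i, -i] == 1L)
      merged$n_trans[i] <- sum(rel[i, -i] == -1L)
    }
  }
  ## phase sets over heterozygous calls: connected components of the relation
  ## graph, 2-colored (cis = same haplotype, trans = opposite); conflicts
  ## leave the component unphased
  hets <- which(merged$genotype == "het")
  color <- rep(NA_integer_, n)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in hets) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid; color[s] <- 0L
    conflict <- FALSE
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      nb <- setdiff(which(rel[i, ] != 0L), i)
      nb <- nb[nb %in% hets]
      for (j in nb) {
        want <- if (rel[i, j] == 1L) color[i] else 1L - color[i]
        if (is.na(comp[j])) {
          comp[j] <- cid; color[j] <- want; queue <- c(queue, j)
        } else if (color[j] != want) conflict <- TRUE
      }
    }
    members <- which(comp == cid)
    if (conflict) {
      merged$gt[members] <- "0/1"
    } else {
      ps <- min(merged$pos[members])
      merged$ps[members] <- ps
      merged$gt[members] <- ifelse(color[members] == 0L, "0|1", "1|0")
    }
  }
  merged
}

#' Annotate merged calls with classifier features
#'
#' Populates the remaining call features: depth and alt-supporting read count
#' at each site (from the pileup), cis/trans counts of other variants in the
#' region, genotype vote entropy, variant type and allele length delta.
#'
#' @param merged output of [mergeWindowCalls()].
#' @param windowCalls the per-window calls the merge was built from.
#' @param source,reference alignment source and reference for pileup stats.
#' @return `merged` with added feature and genotype/phase-set columns.
#' @export
annotateFeatures <- function(merged, windowCalls, source, reference) {
  merged <- .phase_annotate(merged, windowCalls)
  n <- nrow(merged)
  if (n == 0L) {
    for (col in c("gt_entropy", "alt_frac"))
      merged[[col]] <- numeric(0)
    for (col in c("depth", "alt_support", "is_indel", "len_delta"))
      merged[[col]] <- integer(0)
    return(merged)
  }
  merged$depth <- 0L; merged$alt_support <- 0L; merged$alt_frac <- 0
  merged$gt_entropy <- 0; merged$is_indel <- 0L; merged$len_delta <- 0L
  merged$is_indel <- as.integer(nchar(merged$ref) != nchar(merged$alt))
  merged$len_delta <- abs(nchar(merged$alt) - nchar(merged$ref))
  p_het <- merged$votes_het / merged$window_count
  ent <- function(p) ifelse(p <= 0 | p >= 1, 0,
                            -(p * log2(p) + (1 - p) * log2(1 - p)))
  merged$gt_entropy <- ent(p_het)
  chrom <- merged$chrom[1L]
  lo <- max(1L, min(merged$pos) - 5L)
  hi <- max(merged$pos + nchar(merged$ref)) + 5L
  span <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi))
  reads <- .load_reads(source, span)
  refseq <- .get_ref(reference, chrom, 1L, hi + 200L)
  if (nrow(reads)) {
    pe <- .pileup_events(reads, refseq, lo, hi)
    for (i in seq_len(n)) {
      col <- merged$pos[i] - lo + 1L
      ## indels are anchored one base left of the event; support is counted at
      ## the first changed base
      ecol <- if (merged$is_indel[i]) col + 1L else col
      ecol <- min(ecol, length(pe$depth))
      merged$depth[i] <- pe$depth[col]
      kind <- if (!merged$is_indel[i]) "mm"
        else if (nchar(merged$ref[i]) > nchar(merged$alt[i])) "del" else "ins"
      altc <- if (kind == "mm") .base_codes(merged$alt[i]) else NA_integer_
      sup <- 0L
      for (evd in pe$events) {
        if (is.null(evd)) next
        if (kind == "mm") {
          hit <- any(evd$col == ecol & evd$kind == "mm" &
                       !is.na(evd$code) & evd$code == altc)
        } else if (kind == "del") {
          hit <- any(evd$col == ecol & evd$kind == "del")
        } else {
          hit <- any(evd$col == ecol - 1L & evd$kind == "ins")
        }
        if (hit) sup <- sup + 1L
      }
      merged$alt_support[i] <- sup
    }
  }
  merged$alt_frac <- merged$alt_support / pmax(1L, merged$depth)
  merged
}

#' Call variants with the full six-step procedure
#'
#' (1) finds candidate regions, (2) plans overlapping decoding windows,
#' (3) greedy-decodes each window and aligns the generated haplotypes to the
#' reference, (4) merges per-window variants by majority vote, (5) annotates
#' calling features, and (6) scores each call with the random-forest quality
#' model and filters at `minQual` (phred).
#'
#' @param source alignment source (indexed BAM path/`BamFile` or read table).
#' @param reference named character vector, `FaFile` or indexed FASTA path.
#' @param model a trained [HapModel-class].
#' @param classifier a [CalibrationModel-class], or `NULL` to emit raw calls
#'   (quality `NA`, no filtering) e.g. for classifier training.
#' @param span optional length-1 `GRanges` restricting calling; default all
#'   contigs of `reference`.
#' @param minQual phred quality filter (default 10); ignored when
#'   `classifier` is `NULL`.
#' @param seed seed for per-window read downsampling.
#' @param stepSize,upstream,minSupport,slack pipeline tuning parameters (see
#'   [planWindows()], [findCandidateRegions()]).
#' @return data.frame of calls: chrom, pos, ref, alt, gt, ps, qual plus all
#'   feature columns. Failures inside one candidate region are isolated (the
#'   region is skipped with a warning), not fatal to the run.
#' @export
callVariants <- function(source, reference, model, classifier = NULL,
                         span = NULL, minQual = 10, seed = 0L,
                         stepSize = 25L, upstream = 100L, minSupport = 3L,
                         slack = 30L) {
  spans <- if (!is.null(span)) span else {
    ctgs <- .ref_contigs(reference)
    GenomicRanges::GRanges(names(ctgs), IRanges::IRanges(1L, ctgs))
  }
  allcalls <- list()
  for (si in seq_along(spans)) {
    sp <- spans[si]
    regions <- findCandidateRegions(source, reference, sp,
                                    minSupport = minSupport)
    for (ri in seq_along(regions)) {
      reg <- regions[ri]
      res <- tryCatch({
        wins <- planWindows(reg, stepSize = stepSize, upstream = upstream,
                            windowSize = model@config@windowSize)
        wc <- do.call(rbind, lapply(seq_along(wins), function(wi)
          .call_window(model, source, reference, wins[wi], seed = seed,
                       slack = slack)))
        merged <- mergeWindowCalls(wc)
        annotateFeatures(merged, wc, source, reference)
      }, error = function(e) {
        warning("candidate region ", as.character(seqnames(reg)), ":",
                start(reg), "-", end(reg), " failed: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(res) && nrow(res)) allcalls[[length(allcalls) + 1L]] <- res
    }
  }
  calls <- if (length(allcalls)) do.call(rbind, allcalls) else
    annotateFeatures(mergeWindowCalls(.call_window_empty()),
                     .call_window_empty(), source, reference)
  rownames(calls) <- NULL
  ## a variant can fall inside two adjacent candidate regions; keep the
  ## record supported by the most windows
  if (nrow(calls)) {
    key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
    calls <- calls[order(key, -calls$window_count), , drop = FALSE]
    calls <- calls[!duplicated(paste(calls$chrom, calls$pos, calls$ref,
                                     calls$alt, sep = "\r")), , drop = FALSE]
    calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
  }
  if (nrow(calls)) {
    if (!is.null(classifier)) {
      p <- scoreCalls(classifier, calls)
      calls$prob <- p
      calls$qual <- probToPhred(p)
      calls <- calls[calls$qual >= minQual, , drop = FALSE]
    } else {
      calls$prob <- NA_real_
      calls$qual <- NA_real_
    }
  } else {
    calls$prob <- numeric(0)
    calls$qual <- numeric(0)
  }
  rownames(calls) <- NULL
  calls
}

.call_window_empty <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), gt = character(0), kmer_prob = numeric(0),
             pos_in_window = integer(0), win_start = integer(0))
}

## contig name -> length for any reference flavor
.ref_contigs <- function(reference) {
  if (is.character(reference) && !is.null(names(reference)))
    return(vapply(reference, nchar, integer(1)))
  fa <- if (is(reference, "FaFile")) reference else Rsamtools::FaFile(reference)
  info <- Rsamtools::seqinfo(fa)
  stats::setNames(GenomeInfoDb::seqlengths(info), GenomeInfoDb::seqnames(info))
}
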
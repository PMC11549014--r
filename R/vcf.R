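#' Write calls as a VCF 4.2 file
#'
#' Emits one sample with FORMAT `GT` (phased within phase sets, with the `PS`
#' tag) and, when present, the calling features as INFO fields and the
#' calibrated phred quality as QUAL.
#'
#' @param calls data.frame with chrom, pos, ref, alt, gt and optionally ps,
#'   qual and feature columns.
#' @param path output path.
#' @param reference named character vector / `FaFile` / FASTA path, for the
#'   contig header lines.
#' @param sampleName sample column name.
#' @return the path, invisibly.
#' @export
writeVcfFile <- function(calls, path, reference = NULL,
                         sampleName = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=hapformer", con)
  if (!is.null(reference)) {
    ctgs <- .ref_contigs(reference)
    for (ctg in names(ctgs))
      writeLines(sprintf("##contig=<ID=%s,length=%d>", ctg, ctgs[[ctg]]), con)
  }
  info_cols <- intersect(.feature_schema, colnames(calls))
  for (f in info_cols)
    writeLines(sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"Calling feature %s\">",
      toupper(f), f), con)
  writeLines(c(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleName), collapse = "\t"), con)
  if (nrow(calls)) {
    calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt), ,
                   drop = FALSE]
    qual <- if ("qual" %in% colnames(calls))
      ifelse(is.na(calls$qual), ".", sprintf("%.4g", calls$qual))
    else rep(".", nrow(calls))
    info <- if (length(info_cols)) {
      apply(as.data.frame(calls[, info_cols, drop = FALSE]), 1L, function(r)
        paste(paste0(toupper(info_cols), "=", sprintf("%.6g", as.numeric(r))),
              collapse = ";"))
    } else rep(".", nrow(calls))
    ps <- if ("ps" %in% colnames(calls)) calls$ps else rep(NA, nrow(calls))
    fmt <- ifelse(is.na(ps), "GT", "GT:PS")
    smp <- ifelse(is.na(ps), calls$gt, paste0(calls$gt, ":", ps))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t%s\t%s\t%s",
                       calls$chrom, calls$pos, calls$ref, calls$alt, qual,
                       info, fmt, smp), con)
  }
  invisible(path)
}

#' Read a VCF into the call data.frame used throughout the package
#'
#' Thin wrapper over `VariantAnnotation::readVcf` keeping the first ALT
#' allele, the first sample's GT and PS (when present) and QUAL.
#'
#' @param path VCF path (plain or bgzipped).
#' @return data.frame with chrom, pos, ref, alt, gt, ps, qual.
#' @export
readVcfAsCalls <- function(path) {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  n <- length(rr)
  if (n == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), ps = integer(0), qual = numeric(0)))
  alt <- vapply(VariantAnnotation::alt(v), function(a)
    as.character(a[[1L]]), character(1))
  gt <- as.character(VariantAnnotation::geno(v)$GT[, 1L])
  ps <- if ("PS" %in% names(VariantAnnotation::geno(v))) {
    p <- VariantAnnotation::geno(v)$PS[, 1L]
    suppressWarnings(as.integer(p))
  } else rep(NA_integer_, n)
  data.frame(chrom = as.character(seqnames(rr)),
             pos = start(rr),
             ref = as.character(VariantAnnotation::ref(v)),
             alt = alt, gt = gt, ps = ps,
             qual = as.numeric(rr$QUAL),
             stringsAsFactors = FALSE)
}
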
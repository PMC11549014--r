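## ordered feature schema used by the quality classifier
.feature_schema <- c("window_count", "votes_het", "votes_hom", "n_cis",
                     "n_trans", "kmer_min", "kmer_mean", "pos_off_mean",
                     "gt_entropy", "depth", "alt_support", "alt_frac",
                     "is_indel", "len_delta")

.feature_matrix <- function(calls, schema = .feature_schema) {
  missing <- setdiff(schema, colnames(calls))
  if (length(missing))
    stop("calls lack feature columns: ", paste(missing, collapse = ", "))
  as.data.frame(calls[, schema, drop = FALSE])
}

#' Label raw calls against a truth set for classifier training
#'
#' Each unfiltered call is labeled TP when a truth record matches its
#' normalized (chrom, pos, ref, alt) AND its genotype; a correct allele with
#' the wrong genotype is labeled FP for calibration purposes (the evaluation
#' module tallies those separately). Calls outside the confident regions are
#' dropped.
#'
#' @param rawCalls unfiltered calls from [callVariants()] (classifier `NULL`).
#' @param truth truth variant data.frame (chrom, pos, ref, alt, gt).
#' @param confidentBed optional `GRanges` of confident regions.
#' @return data.frame of features plus a `label` factor (TP/FP).
#' @export
buildTrainingSet <- function(rawCalls, truth, confidentBed = NULL) {
  if (!is.null(confidentBed) && nrow(rawCalls)) {
    gr <- GenomicRanges::GRanges(rawCalls$chrom,
                                 IRanges::IRanges(rawCalls$pos, rawCalls$pos))
    rawCalls <- rawCalls[IRanges::overlapsAny(gr, confidentBed), ,
                         drop = FALSE]
  }
  st <- .match_status(rawCalls, truth)
  lab <- ifelse(st$call_status == "tp", "TP", "FP")
  out <- .feature_matrix(rawCalls)
  out$label <- factor(lab, levels = c("FP", "TP"))
  if (!any(out$label == "TP") || !any(out$label == "FP"))
    stop("training set must contain both true- and false-positive calls ",
         "(got ", sum(out$label == "TP"), " TP / ",
         sum(out$label == "FP"), " FP)")
  out
}

#' Fit the random-forest quality model
#'
#' 100 trees with maximum depth 25, balanced class weighting (raw TP/FP ratios
#' vary strongly with model quality). Deterministic given `seed`.
#'
#' @param labeled output of [buildTrainingSet()].
#' @param seed RNG seed for the forest.
#' @param numTrees,maxDepth forest size and depth cap.
#' @return a [CalibrationModel-class].
#' @export
fitCalibration <- function(labeled, seed = 0L, numTrees = 100L,
                           maxDepth = 25L) {
  stopifnot(is.factor(labeled$label), nlevels(labeled$label) == 2L)
  schema <- setdiff(colnames(labeled), "label")
  cw <- as.numeric(1 / table(labeled$label))
  names(cw) <- levels(labeled$label)
  forest <- ranger::ranger(
    label ~ ., data = labeled, num.trees = numTrees, max.depth = maxDepth,
    probability = TRUE, seed = as.integer(seed), num.threads = 1L,
    class.weights = cw)
  new("CalibrationModel", forest = forest, schema = schema,
      meta = list(num_trees = numTrees, max_depth = maxDepth,
                  seed = as.integer(seed),
                  n_tp = sum(labeled$label == "TP"),
                  n_fp = sum(labeled$label == "FP"),
                  version = "hapformer-calibration-1"))
}

#' Score calls with a fitted quality model
#'
#' @param classifier a [CalibrationModel-class].
#' @param calls calls carrying the feature columns of the fitting schema.
#' @return numeric vector of true-call probabilities.
#' @export
scoreCalls <- function(classifier, calls) {
  stopifnot(is(classifier, "CalibrationModel"))
  X <- .feature_matrix(calls, classifier@schema)
  pr <- stats::predict(classifier@forest, data = X, num.threads = 1L)
  as.numeric(pr$predictions[, "TP"])
}

#' Convert a true-call probability to a phred-scaled quality
#'
#' `Q = -10 log10(1 - p)`, capped at 100, so filtering at Q10 keeps exactly
#' the calls with `p >= 0.9`.
#'
#' @param p probability in `[0, 1]`.
#' @return phred-scaled quality.
#' @examples
#' probToPhred(c(0.9, 0.999))
#' @export
probToPhred <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  pmin(100, -10 * log10(1 - p))
}

#' Serialize / restore a calibration model
#'
#' The classifier is stored with its feature schema and a version stamp; the
#' schema is verified at scoring time.
#'
#' @param classifier a [CalibrationModel-class].
#' @param path file path (`.rds`).
#' @export
saveCalibration <- function(classifier, path) {
  saveRDS(list(format = "hapformer-calibration-1",
               schema = classifier@schema, meta = classifier@meta,
               forest = classifier@forest), path)
  invisible(path)
}

#' @rdname saveCalibration
#' @export
loadCalibration <- function(path) {
  x <- readRDS(path)
  stopifnot(identical(x$format, "hapformer-calibration-1"))
  new("CalibrationModel", forest = x$forest, schema = x$schema,
      meta = x$meta)
}
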
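#' Desk-scale end-to-end validation study
#'
#' Runs the whole method at laptop scale on simulated data: simulates
#' independent training, calibration and evaluation samples (50x coverage,
#' 0.1% base error), trains a `tiny`-preset model on roughly 3000 labeled
#' regions, fits the random-forest quality model on raw calls from the
#' calibration sample, then calls variants on the held-out evaluation sample
#' and scores sensitivity/precision for the planted homozygous SNVs at a range
#' of quality thresholds. This mirrors, at toy scale, the published training
#' curves (single-window metrics during training) and the quality-threshold
#' trade-off of the full pipeline.
#'
#' @param seed master seed; all simulation, training, downsampling and forest
#'   seeds derive from it.
#' @param trainContigs,contigKb training-genome size (contigs x kb).
#' @param evalKb,calibKb sizes of the held-out evaluation/calibration
#'   contigs (each split into 20 kb contigs).
#' @param epochs training epochs over the region suite.
#' @param batchSize,maxRate optimizer settings.
#' @param thresholds phred thresholds for the quality sweep.
#' @param verbose print training progress.
#' @return list with `metrics` (one row per threshold: calls emitted,
#'   hom-SNV TP/FP/FN, sensitivity, precision), `homSnvSensitivity` and
#'   `homSnvPrecision` at Q10, `nHomSnv` (truth count), the trained `model`,
#'   `classifier`, `rawEvalCalls`, `evalTruth`, and the training `log`.
#' @export
deskScaleStudy <- function(seed = 1, trainContigs = 8L, contigKb = 20L,
                           evalKb = 80L, calibKb = 100L, epochs = 4L,
                           batchSize = 16L, maxRate = 8e-3,
                           thresholds = c(0, 10, 20, 30), verbose = FALSE) {
  seed <- as.integer(seed) %% 100000L
  kb <- 1000L
  train_s <- simulateSample(simConfig(refLength = contigKb * kb,
                                      nContigs = trainContigs,
                                      seed = seed + 11L))
  calib_s <- simulateSample(simConfig(refLength = 20L * kb,
                                      nContigs = max(1L, calibKb %/% 20L),
                                      seed = seed + 23L))
  eval_s <- simulateSample(simConfig(refLength = 20L * kb,
                                     nContigs = max(1L, evalKb %/% 20L),
                                     seed = seed + 37L))
  suite <- makeRegionSuite(train_s, maxReads = 32L, seed = seed + 5L,
                           replicates = 2L)
  ## hold out a slice of the suite for validation-loss checkpoint selection
  val_idx <- seq(7L, length(suite), by = 37L)
  val <- suite[val_idx]
  suite <- suite[-val_idx]
  model <- hapModel(hapModelConfig("tiny"), seed = seed + 1L)
  steps <- ceiling(length(suite) / batchSize) * epochs
  sched <- lrSchedule(totalSteps = steps, warmupSteps = min(50L, steps %/% 4L),
                      maxRate = maxRate, minRate = maxRate / 10)
  fit <- trainModel(model, suite, schedule = sched, batchSize = batchSize,
                    epochs = epochs, seed = seed + 2L, valExamples = val,
                    evalEvery = max(1L, steps %/% 8L), keepBest = TRUE,
                    verbose = verbose)
  model <- fit$model
  ## quality model: label raw calls on the calibration sample
  raw_calib <- callVariants(calib_s@reads, calib_s@reference, model,
                            classifier = NULL, seed = seed + 3L)
  labeled <- buildTrainingSet(raw_calib, calib_s@truth)
  classifier <- fitCalibration(labeled, seed = seed + 4L)
  ## held-out calling (unfiltered; thresholds applied in the sweep)
  raw_eval <- callVariants(eval_s@reads, eval_s@reference, model,
                           classifier = classifier, minQual = 0,
                           seed = seed + 6L)
  truth <- eval_s@truth
  is_hom_snv <- function(df)
    nchar(df$ref) == 1L & nchar(df$alt) == 1L & .gt_key(df$gt) == "1/1"
  truth_hom <- truth[is_hom_snv(truth), , drop = FALSE]
  tkey <- paste(truth_hom$chrom, truth_hom$pos, truth_hom$ref, truth_hom$alt)
  rows <- lapply(thresholds, function(q) {
    kept <- raw_eval[!is.na(raw_eval$qual) & raw_eval$qual >= q, ,
                     drop = FALSE]
    hom <- kept[is_hom_snv(kept), , drop = FALSE]
    ckey <- paste(hom$chrom, hom$pos, hom$ref, hom$alt)
    tp <- length(intersect(ckey, tkey))
    data.frame(threshold = q, calls = nrow(kept), hom_snv_calls = nrow(hom),
               tp = tp, fp = nrow(hom) - tp, fn = length(tkey) - tp,
               sensitivity = if (length(tkey)) tp / length(tkey) else NA_real_,
               precision = if (nrow(hom)) tp / nrow(hom) else NA_real_)
  })
  metrics <- do.call(rbind, rows)
  q10 <- metrics[metrics$threshold == 10, ]
  list(metrics = metrics,
       homSnvSensitivity = q10$sensitivity[1L],
       homSnvPrecision = q10$precision[1L],
       nHomSnv = nrow(truth_hom),
       model = model, classifier = classifier,
       rawEvalCalls = raw_eval, evalTruth = truth, log = fit$log,
       evalSample = eval_s)
}
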
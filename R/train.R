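## cross-entropy over token logits; returns loss and d(loss)/d(logits)
.ce_loss <- function(logits, ids) {
  L <- nrow(logits)
  stopifnot(length(ids) == L)
  m <- logits[cbind(seq_len(L), max.col(logits, ties.method = "first"))]
  lse <- m + log(rowSums(exp(logits - m)))
  picked <- logits[cbind(seq_len(L), ids + 1L)]
  loss <- mean(lse - picked)
  P <- exp(logits - lse)
  P[cbind(seq_len(L), ids + 1L)] <- P[cbind(seq_len(L), ids + 1L)] - 1
  list(loss = loss, grad = P / L)
}

#' Permutation-minimizing loss for an unordered haplotype pair
#'
#' Haplotypes have no intrinsic order, so the pair of predictions is matched
#' to the pair of targets in whichever of the two configurations yields the
#' lower total token cross-entropy, and gradients flow only through that
#' configuration. The loss is therefore invariant to the order of the targets.
#'
#' @param logits0,logits1 `[L, 256]` token logits from decoders 0 and 1.
#' @param target0,target1 integer token id vectors of length `L`.
#' @return list with `loss` (scalar), `swap` (TRUE if the crossed pairing was
#'   selected), and `grad0`, `grad1` (gradients w.r.t. the two logit
#'   matrices; each decoder's gradient comes from its assigned target only).
#' @export
permutationMinLoss <- function(logits0, logits1, target0, target1) {
  stopifnot(nrow(logits0) == length(target0),
            nrow(logits1) == length(target1),
            length(target0) == length(target1))
  s00 <- .ce_loss(logits0, target0); s11 <- .ce_loss(logits1, target1)
  s01 <- .ce_loss(logits0, target1); s10 <- .ce_loss(logits1, target0)
  straight <- s00$loss + s11$loss
  crossed <- s01$loss + s10$loss
  if (straight <= crossed)
    list(loss = straight, swap = FALSE, grad0 = s00$grad, grad1 = s11$grad)
  else
    list(loss = crossed, swap = TRUE, grad0 = s01$grad, grad1 = s10$grad)
}

#' Learning-rate schedule
#'
#' Linear warm-up from near zero to `maxRate`, then cosine decay to `minRate`.
#' The fine-tuning variant uses a maximum of 1e-5 and minimum of 1e-6.
#'
#' @param totalSteps total optimizer steps.
#' @param warmupSteps warm-up length in steps.
#' @param maxRate,minRate schedule endpoints.
#' @param fineTune use the fine-tuning endpoints (1e-5 to 1e-6).
#' @return list of class `lrSchedule`.
#' @export
lrSchedule <- function(totalSteps, warmupSteps = max(1L, round(totalSteps * 0.05)),
                       maxRate = 5e-5, minRate = 1e-5, fineTune = FALSE) {
  if (fineTune) { maxRate <- 1e-5; minRate <- 1e-6 }
  stopifnot(minRate < maxRate, warmupSteps <= totalSteps)
  structure(list(totalSteps = as.integer(totalSteps),
                 warmupSteps = as.integer(warmupSteps),
                 maxRate = maxRate, minRate = minRate),
            class = "lrSchedule")
}

#' @rdname lrSchedule
#' @param step current step (0 to `totalSteps`).
#' @param schedule an `lrSchedule`.
#' @export
lrAtStep <- function(step, schedule) {
  stopifnot(step >= 0, step <= schedule$totalSteps)
  if (step <= schedule$warmupSteps)
    return(schedule$maxRate * step / schedule$warmupSteps)
  frac <- (step - schedule$warmupSteps) /
    (schedule$totalSteps - schedule$warmupSteps)
  schedule$minRate +
    0.5 * (schedule$maxRate - schedule$minRate) * (1 + cos(pi * frac))
}

## zero the gradients of the cross-attention query/key projections (the
## frozen alignment prior)
.zero_align_grads <- function(g) {
  for (dec in c("dec0", "dec1")) {
    for (l in seq_along(g[[dec]]$layers)) {
      g[[dec]]$layers[[l]]$cross$q$W[] <- 0
      g[[dec]]$layers[[l]]$cross$q$b[] <- 0
      g[[dec]]$layers[[l]]$cross$k$W[] <- 0
      g[[dec]]$layers[[l]]$cross$k$b[] <- 0
    }
  }
  g
}

## forward + backward for one training example; returns loss and gradient tree
.example_grad <- function(params, cfg, arr, t0, t1) {
  ec <- .enc_fwd(params, cfg, arr, train = TRUE)
  mm <- .mem_fwd(params, cfg, ec$Y)
  L <- length(t0)
  in0 <- t0[-L]; in1 <- t1[-L]
  if (identical(t0, t1)) {
    f0 <- .dec_fwd(params$dec0, cfg, mm$Y, in0, train = TRUE)
    f1 <- .dec_fwd(params$dec1, cfg, mm$Y, in1, train = TRUE)
    c0 <- .ce_loss(f0$logits, t0); c1 <- .ce_loss(f1$logits, t1)
    loss <- c0$loss + c1$loss
    g0 <- c0$grad; g1 <- c1$grad
  } else {
    f0 <- .dec_fwd(params$dec0, cfg, mm$Y, in0, train = TRUE)
    f1 <- .dec_fwd(params$dec1, cfg, mm$Y, in1, train = TRUE)
    f0x <- .dec_fwd(params$dec0, cfg, mm$Y, in1, train = TRUE)
    f1x <- .dec_fwd(params$dec1, cfg, mm$Y, in0, train = TRUE)
    straight <- .ce_loss(f0$logits, t0); s2 <- .ce_loss(f1$logits, t1)
    crossed <- .ce_loss(f0x$logits, t1); c2 <- .ce_loss(f1x$logits, t0)
    if (straight$loss + s2$loss <= crossed$loss + c2$loss) {
      loss <- straight$loss + s2$loss
      g0 <- straight$grad; g1 <- s2$grad
    } else {
      loss <- crossed$loss + c2$loss
      g0 <- crossed$grad; g1 <- c2$grad
      f0 <- f0x; f1 <- f1x
    }
  }
  b0 <- .dec_bwd(params$dec0, cfg, f0, g0)
  b1 <- .dec_bwd(params$dec1, cfg, f1, g1)
  mb <- .mem_bwd(params, mm, b0$dM + b1$dM)
  eb <- .enc_bwd(params, cfg, ec, mb$dH)
  list(loss = loss,
       g = list(embed = eb$g$embed, proj = eb$g$proj, enc = eb$g$enc,
                enc_final = eb$g$enc_final, mem = mb$g$mem,
                dec0 = b0$g, dec1 = b1$g))
}

## mean permutation-min teacher-forced loss over a set of examples
.val_loss <- function(params, cfg, examples) {
  r <- .batch_grad_fast(params, cfg,
                        lapply(examples, function(ex)
                          .unpack_region(ex$region)),
                        lapply(examples, `[[`, "t0"),
                        lapply(examples, `[[`, "t1"))
  r$loss / length(examples)
}

## decode a training example and tally validation metrics against its targets
.validate_example <- function(model, ex) {
  arr <- .unpack_region(ex$region)
  pred <- greedyDecode(model, arr)
  t0 <- detokenize(ex$t0); t1 <- detokenize(ex$t1)
  miss <- function(a, b) {
    av <- utf8ToInt(a); bv <- utf8ToInt(b)
    n <- min(length(av), length(bv))
    sum(av[seq_len(n)] != bv[seq_len(n)]) + abs(length(av) - length(bv))
  }
  straight <- miss(pred@hap0, t0) + miss(pred@hap1, t1)
  crossed <- miss(pred@hap0, t1) + miss(pred@hap1, t0)
  base_err <- min(straight, crossed) / (nchar(t0) + nchar(t1))
  ## window-local variant recovery
  refslice <- ex$refslice
  vkey <- function(df) if (nrow(df)) paste(df$pos, df$ref, df$alt) else character(0)
  truth_v <- unique(c(
    vkey(extractVariants(t0, refslice)), vkey(extractVariants(t1, refslice))))
  pred_v <- unique(c(
    vkey(extractVariants(pred@hap0, refslice)),
    vkey(extractVariants(pred@hap1, refslice))))
  list(base_err = base_err,
       tp = length(intersect(truth_v, pred_v)),
       fn = length(setdiff(truth_v, pred_v)),
       fp = length(setdiff(pred_v, truth_v)))
}

#' Train the haplotype model
#'
#' AdamW (betas 0.9/0.99) with the warm-up + cosine learning-rate schedule,
#' the permutation-minimizing pair loss, gradient clipping at norm 1.0, and
#' periodic validation logging (mean base-error rate plus single-window
#' variant sensitivity/precision, computed by greedy decoding without any
#' quality calibration). All randomness (shuffling, dropout) is governed by
#' `seed`, so training is reproducible and resuming from a checkpoint with the
#' same seeds reproduces the next step exactly.
#'
#' @param model a [HapModel-class].
#' @param examples list of training examples from [makeRegionSuite()].
#' @param schedule an [lrSchedule()]; defaults to one epoch over `examples`
#'   with 5% warm-up.
#' @param batchSize regions per optimizer step.
#' @param epochs passes over `examples`.
#' @param seed RNG seed for shuffling and dropout.
#' @param valExamples optional held-out examples for metric logging.
#' @param evalEvery evaluate every this many steps (default: once per epoch).
#' @param weightDecay AdamW decoupled weight decay (matrices only).
#' @param clipNorm global gradient-norm clip.
#' @param keepBest when validation examples are supplied, remember the
#'   parameters at the evaluation with the lowest validation loss and return
#'   those (checkpoint selection by validation loss).
#' @param freezeAlign keep the cross-attention query/key projections fixed at
#'   their positional alignment prior (see the initialization notes in the
#'   methods vignette). At desk scale the alignment geometry is known exactly
#'   and freezing it lets the content pathway converge within a CPU budget;
#'   set `FALSE` to train every parameter.
#' @param optState optimizer state from a previous call, to resume.
#' @param logFile optional JSON-lines metrics log path.
#' @param verbose print progress.
#' @return list with `model` (trained), `log` (data.frame of metrics) and
#'   `optState`.
#' @export
trainModel <- function(model, examples, schedule = NULL, batchSize = 16L,
                       epochs = 1L, seed = 0L, valExamples = NULL,
                       evalEvery = NULL, weightDecay = 0.01, clipNorm = 1,
                       freezeAlign = TRUE, keepBest = FALSE, optState = NULL,
                       logFile = NULL, verbose = FALSE) {
  cfg <- model@config
  params <- model@params
  n <- length(examples)
  steps_per_epoch <- ceiling(n / batchSize)
  total <- steps_per_epoch * epochs
  if (is.null(schedule)) schedule <- lrSchedule(total)
  if (is.null(evalEvery)) evalEvery <- steps_per_epoch
  if (is.null(optState)) optState <- .adamw_init(params)
  logrows <- list()
  best <- list(loss = Inf, params = NULL)
  step <- optState$t
  ## RNG is keyed to the absolute epoch (shuffle) and step (dropout), so a
  ## resumed run reproduces the stream of a continuous one exactly
  epoch_base <- step %/% steps_per_epoch
  .with_seed(seed, {
    for (ep in seq_len(epochs)) {
      set.seed(seed + 104729L * (epoch_base + ep))
      ord <- sample.int(n)
      for (bi in seq_len(steps_per_epoch)) {
        set.seed(seed + 7L * step + 1L)
        idx <- ord[((bi - 1L) * batchSize + 1L):min(bi * batchSize, n)]
        if (cfg@dropout == 0) {
          ## compiled batched kernel (exact match of the R path; see tests)
          b <- .batch_grad_fast(params, cfg,
                                lapply(examples[idx], function(ex)
                                  .unpack_region(ex$region)),
                                lapply(examples[idx], `[[`, "t0"),
                                lapply(examples[idx], `[[`, "t1"))
          loss_sum <- b$loss
          gacc <- b$g
        } else {
          gacc <- NULL
          loss_sum <- 0
          for (i in idx) {
            ex <- examples[[i]]
            r <- .example_grad(params, cfg, .unpack_region(ex$region),
                               ex$t0, ex$t1)
            loss_sum <- loss_sum + r$loss
            gacc <- if (is.null(gacc)) r$g else .tree_add(gacc, r$g)
          }
        }
        if (freezeAlign) gacc <- .zero_align_grads(gacc)
        if (!is.finite(loss_sum))
          stop("non-finite loss at step ", step + 1L,
               "; aborting training (check inputs / learning rate)")
        gacc <- .tree_map(function(x) x / length(idx), gacc)
        gn <- .tree_gnorm(gacc)
        if (gn > clipNorm)
          gacc <- .tree_map(function(x) x * (clipNorm / gn), gacc)
        step <- step + 1L
        lr <- lrAtStep(min(step, schedule$totalSteps), schedule)
        upd <- .adamw_step(params, gacc, optState, lr, wd = weightDecay)
        params <- upd$params
        optState <- upd$state
        if (!is.null(valExamples) &&
            (step %% evalEvery == 0L || step == total)) {
          model@params <- params
          val_loss <- .val_loss(params, cfg, valExamples)
          if (keepBest && val_loss < best$loss)
            best <- list(loss = val_loss, params = params)
          vals <- lapply(valExamples, function(ex) .validate_example(model, ex))
          tp <- sum(vapply(vals, `[[`, numeric(1), "tp"))
          fn <- sum(vapply(vals, `[[`, numeric(1), "fn"))
          fp <- sum(vapply(vals, `[[`, numeric(1), "fp"))
          row <- data.frame(
            step = step, lr = lr,
            train_loss = loss_sum / length(idx),
            val_loss = val_loss,
            base_error = mean(vapply(vals, `[[`, numeric(1), "base_err")),
            sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
            precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
          logrows[[length(logrows) + 1L]] <- row
          if (!is.null(logFile))
            cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), "\n",
                file = logFile, append = TRUE)
          if (verbose)
            message(sprintf(
              "step %d  lr %.2e  loss %.4f  base_err %.4f  sens %.3f  prec %.3f",
              step, lr, row$train_loss, row$base_error,
              row$sensitivity, row$precision))
        } else if (verbose && step %% 10L == 0L) {
          message(sprintf("step %d  lr %.2e  loss %.4f", step, lr,
                          loss_sum / length(idx)))
        }
      }
    }
  })
  model@params <- if (keepBest && !is.null(best$params)) best$params else params
  list(model = model,
       log = if (length(logrows)) do.call(rbind, logrows) else
         data.frame(step = integer(0)),
       optState = optState)
}
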
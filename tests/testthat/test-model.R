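## a micro configuration that keeps gradient checks and causality tests fast
micro_cfg <- function() {
  hapModelConfig("tiny", windowSize = 8L, maxReads = 3L, baseEmbedDim = 4L,
                 embeddingDim = 8L, encoderHeads = 2L, encoderLayers = 1L,
                 decoderDim = 8L, decoderHeads = 2L, decoderLayers = 1L,
                 maxTokens = 5L, ffMult = 2L, dropout = 0)
}

micro_region <- function(seed = 3) {
  set.seed(seed)
  arr <- array(0, c(8, 3, 10))
  arr[, 1, ] <- matrix(runif(80), 8, 10)
  arr[1:4, 2, ] <- matrix(runif(40), 4, 10)
  arr
}

test_that("preset parameter counts land near the published model sizes", {
  expect_lt(abs(paramCount(hapModelConfig("30M")) / 30e6 - 1), 0.20)
  expect_lt(abs(paramCount(hapModelConfig("50M")) / 50e6 - 1), 0.20)
  expect_lt(abs(paramCount(hapModelConfig("100M")) / 100e6 - 1), 0.20)
  ## analytic count matches the instantiated tree
  m <- hapModel(hapModelConfig("tiny"), seed = 1)
  expect_identical(paramCount(m), paramCount(hapModelConfig("tiny")))
  ## paper presets keep decoder model dimension 256 = 4^4
  expect_identical(hapModelConfig("30M")@decoderDim, 256L)
  expect_identical(hapModelConfig("50M")@decoderDim, 256L)
  ## input token size after flattening is d*r
  expect_identical(nrow(m@params$proj$W),
                   m@config@baseEmbedDim * m@config@maxReads)
})

test_that("the encoder treats the read axis non-symmetrically", {
  cfg <- micro_cfg()
  m <- hapModel(cfg, seed = 2)
  arr <- micro_region()
  arr[5:8, 3, ] <- arr[1:4, 2, ]   # a second read elsewhere
  swapped <- arr
  swapped[, 2, ] <- arr[, 3, ]
  swapped[, 3, ] <- arr[, 2, ]
  h1 <- encoderForward(m, arr)
  h2 <- encoderForward(m, swapped)
  expect_identical(dim(h1), c(8L, 8L))
  expect_gt(max(abs(h1 - h2)), 1e-8)   # 2D encoding breaks permutation symmetry
})

test_that("degenerate inputs stay finite and absent cells contribute zero", {
  cfg <- micro_cfg()
  m <- hapModel(cfg, seed = 2)
  h <- encoderForward(m, array(0, c(8, 3, 10)))
  expect_true(all(is.finite(h)))
  ## the embedded value of an all-zero pileup cell is exactly zero, so padded
  ## rows beyond the encoded reads cannot influence the flattened token
  ec <- hapformer:::.enc_fwd(m@params, cfg, micro_region())
  zero_cells <- which(ec$mask == 0)
  E1 <- (hapformer:::.lin_fwd(m@params$embed,
         matrix(micro_region(), 24, 10))$Y +
           hapformer:::.pe2d(8, 3, 4)) * ec$mask
  expect_true(all(E1[zero_cells, ] == 0))
})

test_that("decode steps are normalized, capped and decoder-specific", {
  cfg <- micro_cfg()
  m <- hapModel(cfg, seed = 4)
  mem <- encoderForward(m, micro_region())
  p0 <- decodeStep(m, mem, 0L, c(1L, 7L))
  p1 <- decodeStep(m, mem, 1L, c(1L, 7L))
  expect_equal(sum(p0), 1, tolerance = 1e-5)
  expect_equal(sum(p1), 1, tolerance = 1e-5)
  expect_gt(max(abs(p0 - p1)), 1e-8)   # decoders do not share parameters
  expect_error(decodeStep(m, mem, 0L, rep(0L, cfg@maxTokens)), "cap")
})

test_that("decoding is causal: future tokens never change earlier steps", {
  cfg <- micro_cfg()
  m <- hapModel(cfg, seed = 5)
  mem <- encoderForward(m, micro_region())
  M <- hapformer:::.mem_fwd(m@params, cfg, mem)$Y
  a <- hapformer:::.dec_fwd(m@params$dec0, cfg, M, c(3L, 9L, 100L))
  b <- hapformer:::.dec_fwd(m@params$dec0, cfg, M, c(3L, 9L, 200L))
  ## logits at steps 1..3 depend only on tokens < t
  expect_equal(a$logits[1:3, ], b$logits[1:3, ])
  expect_gt(max(abs(a$logits[4, ] - b$logits[4, ])), 1e-8)
})

test_that("greedy decoding caps at 148 bases, is deterministic, ties go low", {
  m <- hapModel(hapModelConfig("tiny"), seed = 6)
  set.seed(10)
  arr <- array(0, c(150, 32, 10))
  arr[, 1, 1:4] <- t(stats::rmultinom(150, 1, rep(0.25, 4)))
  arr[, 1, 5] <- 1
  p1 <- greedyDecode(m, arr)
  p2 <- greedyDecode(m, arr)
  expect_identical(nchar(p1@hap0), 148L)
  expect_identical(nchar(p1@hap1), 148L)
  expect_identical(p1@tokens0, p2@tokens0)
  expect_true(all(p1@tokenProbs0 > 0 & p1@tokenProbs0 <= 1))
  ## all-equal logits (zeroed output head) -> argmax tie -> lowest id (AAAA)
  m0 <- m
  m0@params$dec0$out$W[] <- 0
  m0@params$dec0$out$b[] <- 0
  p0 <- greedyDecode(m0, arr, nTokens = 3)
  expect_identical(p0@hap0, paste(rep("AAAA", 3), collapse = ""))
})

test_that("analytic gradients match finite differences", {
  cfg <- micro_cfg()
  m <- hapModel(cfg, seed = 2)
  arr <- micro_region()
  t0 <- c(3L, 200L, 17L); t1 <- c(3L, 9L, 255L)
  ## same permutation-minimizing objective the training gradient uses
  loss_fn <- function(params) {
    ec <- hapformer:::.enc_fwd(params, cfg, arr)
    mm <- hapformer:::.mem_fwd(params, cfg, ec$Y)
    ce <- function(pdec, inp, tgt)
      hapformer:::.ce_loss(
        hapformer:::.dec_fwd(pdec, cfg, mm$Y, inp)$logits, tgt)$loss
    min(ce(params$dec0, t0[-3], t0) + ce(params$dec1, t1[-3], t1),
        ce(params$dec0, t1[-3], t1) + ce(params$dec1, t0[-3], t0))
  }
  r <- hapformer:::.example_grad(m@params, cfg, arr, t0, t1)
  paths <- list(c("embed", "W"), c("proj", "W"),
                c("enc", "l1", "attn", "q", "W"), c("enc", "l1", "ln1", "g"),
                c("enc", "l1", "ff", "l1", "W"), c("mem", "W"),
                c("dec0", "tok"), c("dec0", "start"),
                c("dec0", "layers", "l1", "self", "k", "W"),
                c("dec0", "layers", "l1", "cross", "v", "W"),
                c("dec1", "layers", "l1", "ff", "l2", "b"),
                c("dec1", "out", "W"))
  getp <- function(x, pa) { for (k in pa) x <- x[[k]]; x }
  setp <- function(x, pa, v) {
    if (length(pa) == 1L) { x[[pa]] <- v; return(x) }
    x[[pa[1L]]] <- setp(x[[pa[1L]]], pa[-1L], v)
    x
  }
  eps <- 1e-5
  for (pa in paths) {
    g_an <- getp(r$g, pa)
    pv <- getp(m@params, pa)
    set.seed(sum(utf8ToInt(paste(pa, collapse = ""))))
    for (i in sample(length(pv), min(3L, length(pv)))) {
      pv[i] <- pv[i] + eps
      lp <- loss_fn(setp(m@params, pa, pv))
      pv[i] <- pv[i] - 2 * eps
      lm <- loss_fn(setp(m@params, pa, pv))
      pv[i] <- pv[i] + eps
      g_num <- (lp - lm) / (2 * eps)
      denom <- max(1e-6, abs(g_num) + abs(g_an[i]))
      expect_lt(abs(g_num - g_an[i]) / denom, 1e-3,
                label = paste(paste(pa, collapse = "."), i))
    }
  }
})

test_that("checkpoints round-trip weights, config and tokenizer convention", {
  cfg <- micro_cfg()
  m <- hapModel(cfg, seed = 9)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  expect_identical(m2@params, m@params)
  expect_identical(m2@config@decoderDim, cfg@decoderDim)
  arr <- micro_region()
  expect_identical(greedyDecode(m, arr)@tokens0,
                   greedyDecode(m2, arr)@tokens0)
  unlink(f)
})
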
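#' Construct a model configuration
#'
#' Named presets follow the published 30M/50M/100M parameter combinations
#' (encoder layers/heads/embedding dim and decoder layers/heads); both
#' haplotype decoders always have model dimension 256 (= 4^4, the output
#' vocabulary). The `tiny` preset (2 encoder layers, embedding 64, 2 decoder
#' layers, 32 read rows) is designed for CPU-scale testing and is not a
#' published configuration.
#'
#' @param preset one of `"tiny"`, `"30M"`, `"50M"`, `"100M"`.
#' @param ... named overrides for any slot of [HapModelConfig-class], e.g.
#'   `maxReads = 64` or `dropout = 0`.
#' @return a validated [HapModelConfig-class].
#' @examples
#' hapModelConfig("tiny")
#' @export
hapModelConfig <- function(preset = c("tiny", "30M", "50M", "100M"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "tiny" = list(encoderLayers = 2L, encoderHeads = 4L, embeddingDim = 64L,
                  decoderLayers = 2L, decoderHeads = 4L, decoderDim = 64L,
                  maxReads = 32L, ffMult = 4L, dropout = 0),
    "30M"  = list(encoderLayers = 6L, encoderHeads = 8L, embeddingDim = 800L,
                  decoderLayers = 4L, decoderHeads = 4L, decoderDim = 256L,
                  maxReads = 150L, ffMult = 1L, dropout = 0.1),
    "50M"  = list(encoderLayers = 8L, encoderHeads = 8L, embeddingDim = 960L,
                  decoderLayers = 8L, decoderHeads = 4L, decoderDim = 256L,
                  maxReads = 150L, ffMult = 1L, dropout = 0.1),
    "100M" = list(encoderLayers = 10L, encoderHeads = 8L, embeddingDim = 1280L,
                  decoderLayers = 10L, decoderHeads = 8L, decoderDim = 256L,
                  maxReads = 150L, ffMult = 1L, dropout = 0.1))
  args <- utils::modifyList(c(base, list(
    name = preset, baseEmbedDim = 12L, windowSize = 150L,
    kmerSize = 4L, vocabSize = 256L, maxTokens = 37L)), list(...))
  for (s in setdiff(names(args), c("name", "dropout")))
    args[[s]] <- as.integer(args[[s]])
  args$dropout <- as.numeric(args$dropout)
  do.call(new, c(list(Class = "HapModelConfig"), args))
}

.init_params <- function(cfg) {
  d <- cfg@baseEmbedDim; E <- cfg@embeddingDim; Dd <- cfg@decoderDim
  V <- cfg@vocabSize
  enc_layer <- function() list(attn = .mha_init(E), ln1 = .ln_init(E),
                               ff = .ff_init(E, cfg@ffMult), ln2 = .ln_init(E))
  ## pre-norm blocks plus a final layer norm per stack
  dec_layer <- function() list(self = .mha_init(Dd), ln1 = .ln_init(Dd),
                               cross = .mha_init(Dd, alignInit = TRUE,
                                                 nhead = cfg@decoderHeads,
                                                 kmer = cfg@kmerSize),
                               ln2 = .ln_init(Dd),
                               ff = .ff_init(Dd, cfg@ffMult), ln3 = .ln_init(Dd))
  decoder <- function() {
    layers <- lapply(seq_len(cfg@decoderLayers), function(i) dec_layer())
    names(layers) <- paste0("l", seq_along(layers))
    ## token/start embeddings are initialized at a scale comparable to the
    ## unit-amplitude sinusoidal encodings (embedding scaling, as in the
    ## original transformer); tiny embeddings drown in the positional signal
    list(tok = matrix(stats::rnorm(V * Dd, sd = 0.35), V, Dd),
         start = stats::rnorm(Dd, sd = 0.35),
         layers = layers, final = .ln_init(Dd),
         out = .lin_init(Dd, V))
  }
  enc <- lapply(seq_len(cfg@encoderLayers), function(i) enc_layer())
  names(enc) <- paste0("l", seq_along(enc))
  p <- list(embed = .lin_init(10L, d, sd = 0.35),
            proj = .lin_init(d * cfg@maxReads, E),
            enc = enc, enc_final = .ln_init(E),
            mem = .lin_init(E, Dd),
            dec0 = decoder(), dec1 = decoder())
  ## zero-init every residual-branch output projection (the network starts as
  ## an identity-with-clean-signals map and grows the branches it needs) and
  ## keep the positional "ruler" dimensions of the memory and of the decoder
  ## token embeddings free of content at the start, so the cross-attention
  ## alignment prior sees pure position signals
  ## consensus-pooling prior on the flatten projection: its first d output
  ## dimensions average the per-cell embeddings across read rows, so a
  ## column's pooled base consensus is extracted identically no matter which
  ## reads happen to cover it (coverage varies along the window)
  p$proj$W[, seq_len(d)] <- 0
  for (j in seq_len(cfg@maxReads))
    p$proj$W[(j - 1L) * d + seq_len(d), seq_len(d)] <- diag(d) / cfg@maxReads
  ruler <- .align_src_dims(Dd, Dd %/% cfg@decoderHeads)
  for (l in seq_len(cfg@encoderLayers)) {
    p$enc[[l]]$attn$o$W[] <- 0
    p$enc[[l]]$ff$l2$W[] <- 0
  }
  p$mem$W[, ruler] <- 0
  for (dec in c("dec0", "dec1")) {
    p[[dec]]$tok[, ruler] <- 0
    p[[dec]]$start[ruler] <- 0
    for (l in seq_len(cfg@decoderLayers)) {
      p[[dec]]$layers[[l]]$self$o$W[] <- 0
      ## the cross-attention output keeps its fan-in init (zeroing it would
      ## cut the gradient to the value/memory/encoder path entirely) but
      ## writes nothing into the ruler dimensions, so retrieved content never
      ## perturbs the position signals the queries read
      p[[dec]]$layers[[l]]$cross$o$W[, ruler] <- 0
      p[[dec]]$layers[[l]]$ff$l2$W[] <- 0
    }
  }
  p
}

#' Instantiate a haplotype model
#'
#' @param config a [HapModelConfig-class] (see [hapModelConfig()]).
#' @param seed integer seed for weight initialization.
#' @return a [HapModel-class].
#' @examples
#' m <- hapModel(hapModelConfig("tiny"), seed = 1)
#' paramCount(m)
#' @export
hapModel <- function(config, seed = 0L) {
  stopifnot(is(config, "HapModelConfig"))
  set.seed(as.integer(seed))
  new("HapModel", config = config, params = .init_params(config))
}

#' Number of trainable parameters
#'
#' @param x a [HapModel-class] or [HapModelConfig-class]. For a config the
#'   count is computed analytically without allocating weights.
#' @return numeric scalar.
#' @export
paramCount <- function(x) {
  if (is(x, "HapModel")) return(.tree_count(x@params))
  stopifnot(is(x, "HapModelConfig"))
  d <- x@baseEmbedDim; E <- x@embeddingDim; Dd <- x@decoderDim
  V <- x@vocabSize; f <- x@ffMult
  lin <- function(a, b) a * b + b
  mha <- function(D) 4 * lin(D, D)
  ff <- function(D) lin(D, D * f) + lin(D * f, D)
  enc_layer <- mha(E) + ff(E) + 4 * E
  dec_layer <- 2 * mha(Dd) + ff(Dd) + 6 * Dd
  decoder <- V * Dd + Dd + x@decoderLayers * dec_layer + lin(Dd, V) + 2 * Dd
  lin(10, d) + lin(d * x@maxReads, E) + x@encoderLayers * enc_layer + 2 * E +
    lin(E, Dd) + 2 * decoder
}

## cached positional encodings (keyed by dims)
.pe_cache <- new.env(parent = emptyenv())
.pe2d <- function(g, r, d) {
  key <- paste0("2d_", g, "_", r, "_", d)
  if (is.null(.pe_cache[[key]])) .pe_cache[[key]] <- sinusoidal2DPE(g, r, d)
  .pe_cache[[key]]
}
.pe1d <- function(n, d) {
  key <- paste0("1d_", n, "_", d)
  if (is.null(.pe_cache[[key]])) .pe_cache[[key]] <- sinusoidalPE(n, d)
  .pe_cache[[key]]
}

## ---- encoder --------------------------------------------------------------

## arr: [g, r, 10]. Returns encoder output [g, E] plus cache for backprop.
.enc_fwd <- function(params, cfg, arr, train = FALSE) {
  g <- cfg@windowSize; r <- cfg@maxReads; d <- cfg@baseEmbedDim
  stopifnot(identical(dim(arr), c(g, r, 10L)))
  X <- matrix(arr, nrow = g * r, ncol = 10L)   # row index = pos + (read-1)*g
  mask <- as.numeric(rowSums(X != 0) > 0)
  emb <- .lin_fwd(params$embed, X)
  E1 <- (emb$Y + .pe2d(g, r, d)) * mask
  ## flatten read axis: F[p, (j-1)*d + k] = cell embedding
  Fm <- matrix(aperm(array(E1, c(g, r, d)), c(1L, 3L, 2L)), g, r * d)
  pr <- .lin_fwd(params$proj, Fm)
  H <- pr$Y
  caches <- vector("list", cfg@encoderLayers)
  for (l in seq_len(cfg@encoderLayers)) {
    p <- params$enc[[l]]
    n1 <- .ln_fwd(p$ln1, H)
    at <- .mha_fwd(p$attn, n1$Y, n1$Y, cfg@encoderHeads)
    dr1 <- .drop_fwd(at$Y, cfg@dropout, train)
    H1 <- H + dr1$Y
    n2 <- .ln_fwd(p$ln2, H1)
    ff <- .ff_fwd(p$ff, n2$Y)
    dr2 <- .drop_fwd(ff$Y, cfg@dropout, train)
    caches[[l]] <- list(n1 = n1, at = at, dr1 = dr1, n2 = n2, ff = ff,
                        dr2 = dr2)
    H <- H1 + dr2$Y
  }
  fin <- .ln_fwd(params$enc_final, H)
  list(Y = fin$Y, mask = mask, emb = emb, pr = pr, layers = caches,
       fin = fin)
}

.enc_bwd <- function(params, cfg, cache, dH) {
  g <- cfg@windowSize; r <- cfg@maxReads; d <- cfg@baseEmbedDim
  glayers <- vector("list", cfg@encoderLayers)
  names(glayers) <- names(params$enc)
  bf <- .ln_bwd(params$enc_final, cache$fin, dH)
  dH <- bf$dX
  for (l in rev(seq_len(cfg@encoderLayers))) {
    p <- params$enc[[l]]; cc <- cache$layers[[l]]
    dff <- .drop_bwd(cc$dr2, dH)
    fb <- .ff_bwd(p$ff, cc$ff, dff)
    b2 <- .ln_bwd(p$ln2, cc$n2, fb$dX)
    dH1 <- dH + b2$dX
    dat <- .drop_bwd(cc$dr1, dH1)
    ab <- .mha_bwd(p$attn, cc$at, dat)
    b1 <- .ln_bwd(p$ln1, cc$n1, ab$dXq + ab$dXkv)
    dH <- dH1 + b1$dX
    glayers[[l]] <- list(attn = ab$g, ln1 = b1$g, ff = fb$g, ln2 = b2$g)
  }
  pb <- .lin_bwd(params$proj, cache$pr, dH)
  dF <- pb$dX
  dE1 <- matrix(aperm(array(dF, c(g, d, r)), c(1L, 3L, 2L)), g * r, d)
  dE1 <- dE1 * cache$mask
  eb <- .lin_bwd(params$embed, cache$emb, dE1)
  list(g = list(embed = eb$g, proj = pb$g, enc = glayers,
                enc_final = bf$g))
}

## memory projection + 1D positional encoding over the g axis
.mem_fwd <- function(params, cfg, H) {
  m <- .lin_fwd(params$mem, H)
  list(Y = m$Y + .pe1d(nrow(m$Y), cfg@decoderDim), m = m)
}

.mem_bwd <- function(params, cache, dM) {
  b <- .lin_bwd(params$mem, cache$m, dM)
  list(dH = b$dX, g = list(mem = b$g))
}

## ---- decoder --------------------------------------------------------------

## input_ids: 0-based token ids fed as teacher-forced/previous tokens.
## The decoder input is [start, emb(input_ids)] (length L+1) and logits row t
## predicts the t-th next token.
.dec_fwd <- function(pdec, cfg, M, input_ids, train = FALSE) {
  L <- length(input_ids) + 1L
  if (L > cfg@maxTokens)
    stop("decoder prefix exceeds the ", cfg@maxTokens, "-token cap")
  Dd <- cfg@decoderDim
  X <- matrix(0, L, Dd)
  X[1L, ] <- pdec$start
  if (L > 1L) X[2L:L, ] <- pdec$tok[input_ids + 1L, , drop = FALSE]
  ## decoder positions are encoded in base-space coordinates (token t starts
  ## at window offset 4*(t-1)), so the query and memory sinusoids share the
  ## same frequency grid and cross-attention alignment is a fixed rotation
  X <- X + .pe1d(4L * cfg@maxTokens, Dd)[seq(1L, by = 4L, length.out = L), ,
                                         drop = FALSE]
  caches <- vector("list", cfg@decoderLayers)
  for (l in seq_len(cfg@decoderLayers)) {
    p <- pdec$layers[[l]]
    n1 <- .ln_fwd(p$ln1, X)
    sa <- .mha_fwd(p$self, n1$Y, n1$Y, cfg@decoderHeads, causal = TRUE)
    dr1 <- .drop_fwd(sa$Y, cfg@dropout, train)
    X1 <- X + dr1$Y
    n2 <- .ln_fwd(p$ln2, X1)
    ca <- .mha_fwd(p$cross, n2$Y, M, cfg@decoderHeads)
    dr2 <- .drop_fwd(ca$Y, cfg@dropout, train)
    X2 <- X1 + dr2$Y
    n3 <- .ln_fwd(p$ln3, X2)
    ff <- .ff_fwd(p$ff, n3$Y)
    dr3 <- .drop_fwd(ff$Y, cfg@dropout, train)
    caches[[l]] <- list(n1 = n1, sa = sa, dr1 = dr1, n2 = n2, ca = ca,
                        dr2 = dr2, n3 = n3, ff = ff, dr3 = dr3)
    X <- X2 + dr3$Y
  }
  fin <- .ln_fwd(pdec$final, X)
  out <- .lin_fwd(pdec$out, fin$Y)
  list(logits = out$Y, out = out, layers = caches, fin = fin, L = L,
       input_ids = input_ids)
}

.dec_bwd <- function(pdec, cfg, cache, dLogits) {
  ob <- .lin_bwd(pdec$out, cache$out, dLogits)
  bf <- .ln_bwd(pdec$final, cache$fin, ob$dX)
  dX <- bf$dX
  dM <- NULL
  glayers <- vector("list", cfg@decoderLayers)
  names(glayers) <- names(pdec$layers)
  for (l in rev(seq_len(cfg@decoderLayers))) {
    p <- pdec$layers[[l]]; cc <- cache$layers[[l]]
    dff <- .drop_bwd(cc$dr3, dX)
    fb <- .ff_bwd(p$ff, cc$ff, dff)
    b3 <- .ln_bwd(p$ln3, cc$n3, fb$dX)
    dX2 <- dX + b3$dX
    dca <- .drop_bwd(cc$dr2, dX2)
    cb <- .mha_bwd(p$cross, cc$ca, dca)
    dM <- if (is.null(dM)) cb$dXkv else dM + cb$dXkv
    b2 <- .ln_bwd(p$ln2, cc$n2, cb$dXq)
    dX1 <- dX2 + b2$dX
    dsa <- .drop_bwd(cc$dr1, dX1)
    sb <- .mha_bwd(p$self, cc$sa, dsa)
    b1 <- .ln_bwd(p$ln1, cc$n1, sb$dXq + sb$dXkv)
    dX <- dX1 + b1$dX
    glayers[[l]] <- list(self = sb$g, ln1 = b1$g, cross = cb$g, ln2 = b2$g,
                         ff = fb$g, ln3 = b3$g)
  }
  L <- cache$L
  dtok <- matrix(0, nrow(pdec$tok), ncol(pdec$tok))
  if (L > 1L) {
    ids <- cache$input_ids + 1L
    for (t in seq_along(ids))
      dtok[ids[t], ] <- dtok[ids[t], ] + dX[t + 1L, ]
  }
  list(dM = dM,
       g = list(tok = dtok, start = dX[1L, ], layers = glayers,
                final = bf$g, out = ob$g))
}

## ---- public forward API ----------------------------------------------------

#' Run the encoder over one encoded region
#'
#' Embeds each pileup cell in `d` dimensions, adds the 2D (position, read)
#' sinusoidal encoding, flattens along the read axis to tokens of size `d*r`,
#' projects to the encoder embedding dimension, and applies the transformer
#' encoder. Cells that are all zero (no aligned base) contribute exactly zero
#' to the flattened token.
#'
#' @param model a [HapModel-class].
#' @param region an [EncodedRegion-class] or a bare `[g, r, 10]` array.
#' @return numeric matrix `[g, embeddingDim]` of encoder outputs.
#' @export
encoderForward <- function(model, region) {
  arr <- if (is(region, "EncodedRegion")) region@array else region
  .enc_fwd(model@params, model@config, arr)$Y
}

#' One autoregressive decoding step
#'
#' Projects the encoder output to the decoder dimension (adding the standard
#' 1D positional encoding), runs the selected haplotype decoder over the
#' previous tokens, and returns the next-token probability distribution.
#'
#' @param model a [HapModel-class].
#' @param memory encoder output from [encoderForward()].
#' @param decoderId 0 or 1 (the two decoders do not share parameters).
#' @param prevTokens integer vector of already-generated token ids (0-based);
#'   at most 36 (a 37th token would exceed the decoding cap).
#' @return numeric vector of 256 probabilities summing to 1.
#' @export
decodeStep <- function(model, memory, decoderId, prevTokens = integer(0)) {
  stopifnot(decoderId %in% c(0L, 1L))
  cfg <- model@config
  if (length(prevTokens) >= cfg@maxTokens)
    stop("cannot decode past the ", cfg@maxTokens, "-token cap")
  M <- .mem_fwd(model@params, cfg, memory)$Y
  pdec <- if (decoderId == 0L) model@params$dec0 else model@params$dec1
  fw <- .dec_fwd(pdec, cfg, M, as.integer(prevTokens))
  logits <- fw$logits[fw$L, ]
  p <- exp(logits - max(logits))
  p / sum(p)
}

#' Greedy haplotype decoding for one window
#'
#' Standard greedy decoding: at each step the single 4-mer with the highest
#' predicted probability is appended (ties broken toward the lowest token id),
#' until `nTokens` tokens (default the 37-token / 148-base cap) have been
#' generated, for each of the two haplotype decoders.
#'
#' @param model a [HapModel-class].
#' @param region an [EncodedRegion-class].
#' @param nTokens number of tokens to generate (at most 37).
#' @return a [HaplotypePrediction-class].
#' @export
greedyDecode <- function(model, region, nTokens = NULL) {
  cfg <- model@config
  if (is.null(nTokens)) nTokens <- cfg@maxTokens
  nTokens <- min(as.integer(nTokens), cfg@maxTokens)
  arr <- if (is(region, "EncodedRegion")) region@array else region
  pes <- .cpp_pes(cfg)
  res <- .nn_greedy_cpp(.flatten_params(model@params),
                        matrix(arr, cfg@windowSize * cfg@maxReads, 10L),
                        .cpp_cfg(cfg), pes$pe2d, pes$pe_mem, pes$pe_dec,
                        nTokens)
  h0 <- list(ids = res$ids0, probs = res$probs0)
  h1 <- list(ids = res$ids1, probs = res$probs1)
  win <- if (is(region, "EncodedRegion")) region@window else
    GenomicRanges::GRanges("unknown", IRanges::IRanges(1, dim(arr)[1L]))
  new("HaplotypePrediction", window = win,
      hap0 = detokenize(h0$ids), hap1 = detokenize(h1$ids),
      tokens0 = h0$ids, tokens1 = h1$ids,
      tokenProbs0 = h0$probs, tokenProbs1 = h1$probs)
}

## ---- checkpoints -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' Checkpoints carry the weights, the full configuration, and the tokenizer
#' convention so a saved model is self-describing.
#'
#' @param model a [HapModel-class].
#' @param path file path (`.rds`).
#' @export
saveCheckpoint <- function(model, path) {
  cfg <- model@config
  slots <- slotNames(cfg)
  cfg_list <- stats::setNames(lapply(slots, function(s) slot(cfg, s)), slots)
  saveRDS(list(format = "hapformer-checkpoint-1",
               tokenizer = list(kmer = 4L, base_order = "ACGT",
                                endian = "big"),
               config = cfg_list, params = model@params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return `loadCheckpoint()`: the restored [HapModel-class].
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  stopifnot(identical(x$format, "hapformer-checkpoint-1"))
  cfgl <- x$config
  cfg <- do.call(hapModelConfig,
                 c(list(preset = cfgl$name),
                   cfgl[setdiff(names(cfgl), "name")]))
  new("HapModel", config = cfg, params = x$params)
}

## ---- fast-path glue ---------------------------------------------------------

## flatten the nested parameter tree to a named list with dot-joined paths
## (the layout the C++ kernel indexes by)
.flatten_params <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    for (nm in names(x)) {
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      out <- c(out, .flatten_params(x[[nm]], key))
    }
    out
  } else {
    stats::setNames(list(x), prefix)
  }
}

## rebuild a gradient tree shaped like `template` from a flat named list
.unflatten_like <- function(template, flat, prefix = "") {
  if (is.list(template)) {
    out <- template
    for (nm in names(template)) {
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      out[[nm]] <- .unflatten_like(template[[nm]], flat, key)
    }
    out
  } else {
    g <- flat[[prefix]]
    if (!is.null(dim(template)) && is.null(dim(g)))
      dim(g) <- dim(template)
    g
  }
}

.cpp_cfg <- function(cfg) {
  list(g = cfg@windowSize, r = cfg@maxReads, d = cfg@baseEmbedDim,
       E = cfg@embeddingDim, Dd = cfg@decoderDim, he = cfg@encoderHeads,
       hd = cfg@decoderHeads, le = cfg@encoderLayers, ld = cfg@decoderLayers,
       ff = cfg@ffMult, V = cfg@vocabSize, maxT = cfg@maxTokens)
}

.cpp_pes <- function(cfg) {
  list(pe2d = .pe2d(cfg@windowSize, cfg@maxReads, cfg@baseEmbedDim),
       pe_mem = .pe1d(cfg@windowSize, cfg@decoderDim),
       pe_dec = .pe1d(4L * cfg@maxTokens,
                      cfg@decoderDim)[seq(1L, by = 4L,
                                          length.out = cfg@maxTokens), ,
                                      drop = FALSE])
}

## batched loss+gradient through the compiled kernel
.batch_grad_fast <- function(params, cfg, arrs, t0s, t1s) {
  g <- cfg@windowSize; r <- cfg@maxReads
  Xs <- lapply(arrs, function(a) matrix(a, g * r, 10L))
  pes <- .cpp_pes(cfg)
  res <- .nn_batch_grad_cpp(.flatten_params(params), Xs, t0s, t1s,
                            .cpp_cfg(cfg), pes$pe2d, pes$pe_mem, pes$pe_dec)
  list(loss = res$loss, g = .unflatten_like(params, res$grads))
}
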
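## Minimal transformer building blocks with explicit forward/backward passes.
## All functions are pure: parameters and caches are plain nested lists of
## numeric matrices/vectors, so training is reproducible and the analytic
## gradients can be checked against finite differences (see tests).

## fan-in (LeCun/Xavier) scaling keeps activations and attention
## contributions at unit scale for any model dimension
.lin_init <- function(n_in, n_out, sd = 1 / sqrt(n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
       b = numeric(n_out))
}

.lin_fwd <- function(p, X) {
  Y <- X %*% p$W
  Y <- Y + rep(p$b, each = nrow(Y))
  list(Y = Y, X = X)
}

.lin_bwd <- function(p, cache, dY) {
  list(dX = tcrossprod(dY, p$W),
       g = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

## exact GeLU: x * Phi(x)
.gelu_fwd <- function(X) list(Y = X * stats::pnorm(X), X = X)
.gelu_bwd <- function(cache, dY) {
  X <- cache$X
  dY * (stats::pnorm(X) + X * stats::dnorm(X))
}

.ln_init <- function(d) list(g = rep(1, d), b = numeric(d))

.ln_fwd <- function(p, X, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + eps)
  Xh <- Xc * inv
  Y <- Xh * rep(p$g, each = nrow(X)) + rep(p$b, each = nrow(X))
  list(Y = Y, Xh = Xh, inv = inv)
}

.ln_bwd <- function(p, cache, dY) {
  Xh <- cache$Xh
  dXh <- dY * rep(p$g, each = nrow(dY))
  m1 <- rowMeans(dXh)
  m2 <- rowMeans(dXh * Xh)
  dX <- (dXh - m1 - Xh * m2) * cache$inv
  list(dX = dX, g = list(g = colSums(dY * Xh), b = colSums(dY)))
}

.softmax_rows <- function(S) {
  S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S)
  E / rowSums(E)
}

## rotation of the sinusoidal positional basis by `delta` positions:
## PE(p + delta) == PE(p) %*% .pe_shift(d, delta), exactly, for the standard
## encoding (each frequency pair rotates by delta * omega_i)
.pe_shift <- function(d, delta) {
  R <- matrix(0, d, d)
  i <- seq_len(d %/% 2L) - 1
  om <- 1 / (10000^(2 * i / d))
  a <- delta * om
  s <- seq(1L, d, by = 2L)
  R[cbind(s, s)] <- cos(a)
  R[cbind(s + 1L, s + 1L)] <- cos(a)
  R[cbind(s, s + 1L)] <- -sin(a)     # sin-row contribution to the cos output
  R[cbind(s + 1L, s)] <- sin(a)      # cos-row contribution to the sin output
  R
}

## Cross-attention alignment prior. Decoder queries and memory keys carry
## sinusoidal position signals on the same base-coordinate grid, and a token
## covers `kmer` consecutive bases, so head h is initialized to attend to
## base offset (h-1) mod kmer of the current token: its query block is the
## positional-basis rotation by that offset (scaled), its key block the
## scaled identity. The initial attention is then sharply diagonal with a
## per-head offset, and training only has to learn the content mapping; the
## alignment itself remains fully trainable.
.mha_init <- function(d_model, alignInit = FALSE, nhead = 1L, kmer = 4L,
                      alignScale = 2) {
  out <- list(q = .lin_init(d_model, d_model), k = .lin_init(d_model, d_model),
              v = .lin_init(d_model, d_model), o = .lin_init(d_model, d_model))
  if (alignInit) {
    hd <- d_model %/% nhead
    ## route a frequency ladder with low aliasing over a 150-position window
    ## into every head's slice (the key projection may read any input
    ## dimension, so each head gets full positional resolution); interleaved
    ## pairs keep the position kernel sharp with small sidelobes
    src <- .align_src_dims(d_model, hd)
    for (h in seq_len(nhead)) {
      idx <- ((h - 1L) * hd + 1L):(h * hd)
      R <- .pe_shift(d_model, (h - 1L) %% kmer)
      for (j in seq_len(hd)) {
        out$k$W[src[j], idx[j]] <- out$k$W[src[j], idx[j]] + alignScale
        out$q$W[, idx[j]] <- out$q$W[, idx[j]] + alignScale * R[, src[j]]
      }
    }
  }
  out
}

## sinusoid dimensions used as the positional "ruler" by the cross-attention
## alignment prior: every second frequency pair, highest first
.align_src_dims <- function(d_model, hd) {
  pairs <- seq(0L, by = 2L, length.out = hd %/% 2L)
  pairs <- pairs[2L * pairs + 2L <= d_model]
  as.vector(rbind(2L * pairs + 1L, 2L * pairs + 2L))
}

## Multi-head attention. Xq [Tq, D] queries, Xkv [Tk, D] keys/values.
## causal=TRUE applies the standard lower-triangular mask (requires Tq==Tk).
.mha_fwd <- function(p, Xq, Xkv, nhead, causal = FALSE) {
  D <- ncol(Xq); hd <- D %/% nhead; scale <- 1 / sqrt(hd)
  q <- .lin_fwd(p$q, Xq); k <- .lin_fwd(p$k, Xkv); v <- .lin_fwd(p$v, Xkv)
  Tq <- nrow(Xq); Tk <- nrow(Xkv)
  A <- vector("list", nhead)
  O <- matrix(0, Tq, D)
  for (h in seq_len(nhead)) {
    idx <- ((h - 1L) * hd + 1L):(h * hd)
    S <- tcrossprod(q$Y[, idx, drop = FALSE], k$Y[, idx, drop = FALSE]) * scale
    if (causal) S[upper.tri(S)] <- -Inf
    A[[h]] <- .softmax_rows(S)
    O[, idx] <- A[[h]] %*% v$Y[, idx, drop = FALSE]
  }
  o <- .lin_fwd(p$o, O)
  list(Y = o$Y, q = q, k = k, v = v, A = A, O = O, nhead = nhead, hd = hd,
       scale = scale)
}

.mha_bwd <- function(p, cache, dY) {
  ob <- .lin_bwd(p$o, list(X = cache$O), dY)
  dO <- ob$dX
  nhead <- cache$nhead; hd <- cache$hd
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- matrix(0, nrow(cache$k$Y), ncol(dO))
  dV <- dK
  for (h in seq_len(nhead)) {
    idx <- ((h - 1L) * hd + 1L):(h * hd)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$v$Y[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(A * dA))
    dQ[, idx] <- (dS %*% cache$k$Y[, idx, drop = FALSE]) * cache$scale
    dK[, idx] <- crossprod(dS, cache$q$Y[, idx, drop = FALSE]) * cache$scale
  }
  qb <- .lin_bwd(p$q, list(X = cache$q$X), dQ)
  kb <- .lin_bwd(p$k, list(X = cache$k$X), dK)
  vb <- .lin_bwd(p$v, list(X = cache$v$X), dV)
  list(dXq = qb$dX, dXkv = kb$dX + vb$dX,
       g = list(q = qb$g, k = kb$g, v = vb$g, o = ob$g))
}

.ff_init <- function(d_model, mult = 4L) {
  list(l1 = .lin_init(d_model, d_model * mult),
       l2 = .lin_init(d_model * mult, d_model))
}

.ff_fwd <- function(p, X) {
  a <- .lin_fwd(p$l1, X)
  g <- .gelu_fwd(a$Y)
  b <- .lin_fwd(p$l2, g$Y)
  list(Y = b$Y, a = a, g = g, b = b)
}

.ff_bwd <- function(p, cache, dY) {
  bb <- .lin_bwd(p$l2, cache$b, dY)
  dg <- .gelu_bwd(cache$g, bb$dX)
  ab <- .lin_bwd(p$l1, cache$a, dg)
  list(dX = ab$dX, g = list(l1 = ab$g, l2 = bb$g))
}

## inverted dropout; p = drop probability. Identity when p == 0 or !train.
.drop_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - p) / (1 - p),
                 nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}

.drop_bwd <- function(cache, dY) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

## ---- positional encodings -------------------------------------------------

#' Sinusoidal positional encodings
#'
#' `sinusoidalPE()` is the standard 1D transformer encoding. `sinusoidal2DPE()`
#' splits the channel dimension in half: the first half indexes genomic
#' position, the second half indexes the read row, so the encoder can
#' distinguish both axes of the pileup.
#'
#' @param n Number of positions.
#' @param d Number of channels (even).
#' @return `sinusoidalPE()`: an `[n, d]` matrix.
#' @keywords internal
sinusoidalPE <- function(n, d) {
  stopifnot(d %% 2L == 0L)
  pos <- seq_len(n) - 1
  i <- seq_len(d %/% 2L) - 1
  freq <- 1 / (10000^(2 * i / d))
  ang <- outer(pos, freq)
  P <- matrix(0, n, d)
  P[, seq(1L, d, by = 2L)] <- sin(ang)
  P[, seq(2L, d, by = 2L)] <- cos(ang)
  P
}

#' @rdname sinusoidalPE
#' @param g,r Number of genomic positions and read rows.
#' @return `sinusoidal2DPE()`: a `[g*r, d]` matrix whose row for cell
#'   (position p, read j) is at index `p + (j-1)*g`.
#' @keywords internal
sinusoidal2DPE <- function(g, r, d) {
  stopifnot(d %% 2L == 0L)
  half <- d %/% 2L
  Pg <- sinusoidalPE(g, half)
  Pr <- sinusoidalPE(r, half)
  cbind(Pg[rep(seq_len(g), times = r), , drop = FALSE],
        Pr[rep(seq_len(r), each = g), , drop = FALSE])
}

## ---- parameter-tree utilities --------------------------------------------

.tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) .tree_map(f, e)) else f(x)
}

.tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- .tree_map2(f, x[[i]], y[[i]])
    out
  } else f(x, y)
}

.tree_add <- function(x, y) .tree_map2(`+`, x, y)

.tree_count <- function(x) {
  if (is.list(x)) sum(vapply(x, .tree_count, numeric(1))) else length(x)
}

.tree_zeros_like <- function(x) .tree_map(function(e) e * 0, x)

## global gradient L2 norm over a tree
.tree_gnorm <- function(g) {
  s <- 0
  acc <- function(x) { s <<- s + sum(x * x); x }
  invisible(.tree_map(acc, g))
  sqrt(s)
}

## ---- AdamW ----------------------------------------------------------------

.adamw_init <- function(params) {
  list(m = .tree_zeros_like(params), v = .tree_zeros_like(params), t = 0L)
}

## Decoupled weight decay applied to matrices only (biases and layer-norm
## parameters are vectors and are exempt, as is conventional).
.adamw_step <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.99, eps = 1e-8, wd = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    step <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    if (!is.null(dim(p))) step <- step + lr * wd * p
    list(p = p - step, m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else upd(p, g, m, v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
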
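# Desk-scale reference implementation of the divided depth/space attention
# encoder for 2.5D patches.
#
# A 2.5D patch (F depth slices of H x W RGB) is tokenized into N
# non-overlapping P x P tiles per slice plus one classification token.
# Every encoder block applies depth ("temporal") attention -- each patch
# token attends to the classification token and to the tokens at its own
# spatial location across all F slices -- then spatial attention within
# its own slice, then a two-layer GELU MLP, all with residual connections
# and pre-layer-norm projections. Weight layout and shapes are pure
# functions of the configuration, and all initialization is drawn from a
# seeded generator so runs are reproducible.

#' Encoder configuration
#'
#' @param P patch side in pixels.
#' @param D embedding dimension (divisible by `A`).
#' @param A number of attention heads.
#' @param L number of encoder blocks.
#' @param F number of depth slices in a 2.5D patch.
#' @param H,W spatial size of one slice; both divisible by `P`.
#' @param mlpRatio hidden width of the block MLP as a multiple of `D`.
#' @param seed integer seed for weight initialization.
#' @return a validated list of class `EncoderConfig` with derived fields
#'   `N` (tiles per slice) and `Dh` (per-head dimension).
#' @export
encoderConfig <- function(P = 16L, D = 64L, A = 4L, L = 2L, F = 4L,
                          H = 32L, W = 32L, mlpRatio = 2, seed = 1L) {
  if (D %% A != 0L) stop("D must be divisible by A")
  if (H %% P != 0L || W %% P != 0L) stop("H and W must be divisible by P")
  if (F < 1L) stop("F must be >= 1")
  cfg <- list(P = as.integer(P), D = as.integer(D), A = as.integer(A),
              L = as.integer(L), F = as.integer(F), H = as.integer(H),
              W = as.integer(W), mlpRatio = mlpRatio, seed = as.integer(seed),
              N = as.integer((H %/% P) * (W %/% P)), Dh = as.integer(D %/% A))
  class(cfg) <- "EncoderConfig"
  cfg
}

# token row index for spatial position p (1..N) at slice t (1..F);
# row 1 is the classification token
tokenIndex <- function(p, t, N) 1L + (t - 1L) * N + p

#' Initialize encoder weights
#'
#' All matrices are drawn N(0, 0.02) from a generator seeded by
#' `cfg$seed`; layer-norm gains start at 1 and biases at 0.
#'
#' @param cfg an [encoderConfig()].
#' @return list with the embedding `E` (D x 3P^2), positional table `pos`
#'   ((N F + 1) x D), classification token `cls`, and per-block weights.
#' @export
initEncoder <- function(cfg) {
  withSeed(cfg$seed, {
    rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    proj <- function() lapply(seq_len(cfg$A), function(a) rmat(cfg$Dh, cfg$D))
    ln <- function() list(g = rep(1, cfg$D), b = rep(0, cfg$D))
    blocks <- lapply(seq_len(cfg$L), function(l) list(
      lnT = ln(), WqT = proj(), WkT = proj(), WvT = proj(), WoT = rmat(cfg$D, cfg$D),
      lnS = ln(), WqS = proj(), WkS = proj(), WvS = proj(), WoS = rmat(cfg$D, cfg$D),
      lnM = ln(), W1 = rmat(round(cfg$mlpRatio * cfg$D), cfg$D),
      b1 = rep(0, round(cfg$mlpRatio * cfg$D)),
      W2 = rmat(cfg$D, round(cfg$mlpRatio * cfg$D)), b2 = rep(0, cfg$D)))
    list(E = rmat(cfg$D, 3L * cfg$P^2),
         pos = rmat(cfg$N * cfg$F + 1L, cfg$D),
         cls = stats::rnorm(cfg$D, sd = 0.02),
         blocks = blocks)
  })
}

#' Tokenize a 2.5D patch
#'
#' Each P x P x 3 tile of each depth slice is flattened (row-major within
#' the tile, channels last), linearly embedded by `E`, and summed with its
#' spatiotemporal positional embedding; the classification token (with its
#' own positional row) is prepended.
#'
#' @param patch array of shape F x H x W x 3 (a [Patch25D-class] `data`
#'   slot works directly when its dimensions match the config).
#' @param cfg an [encoderConfig()].
#' @param weights an [initEncoder()] weight set.
#' @param tileOffset integer c(row0, col0) tile offset of a cropped view
#'   into the positional table (0-based, in tile units); used for local
#'   distillation views.
#' @param fullTilesWH c(tilesY, tilesX) of the full view the positional
#'   table was laid out for; defaults to the config's own tiling.
#' @return (N F + 1) x D token matrix with attribute `N`, `F`.
#' @export
tokenizePatch <- function(patch, cfg, weights, tileOffset = c(0L, 0L),
                          fullTilesWH = NULL) {
  d <- dim(patch)
  if (length(d) != 4L) stop("patch must be F x H x W x C")
  if (d[2] %% cfg$P != 0L || d[3] %% cfg$P != 0L)
    stop("slice dimensions not divisible by the patch size P")
  Fv <- d[1]
  ty <- d[2] %/% cfg$P; tx <- d[3] %/% cfg$P
  N <- ty * tx
  if (is.null(fullTilesWH)) fullTilesWH <- c(cfg$H %/% cfg$P, cfg$W %/% cfg$P)
  tokens <- matrix(0, N * Fv + 1L, cfg$D)
  tokens[1, ] <- weights$cls + weights$pos[1, ]
  for (t in seq_len(Fv)) for (py in seq_len(ty)) for (px in seq_len(tx)) {
    tile <- patch[t, ((py - 1) * cfg$P + 1):(py * cfg$P),
                  ((px - 1) * cfg$P + 1):(px * cfg$P), , drop = FALSE]
    # row-major flatten: x fastest, then y, channels last
    x <- as.vector(aperm(array(tile, dim(tile)[2:4]), c(2, 1, 3)))
    p <- (py - 1L) * tx + px
    pFull <- (py - 1L + tileOffset[1]) * fullTilesWH[2] + px + tileOffset[2]
    row <- tokenIndex(p, t, N)
    tokens[row, ] <- as.vector(weights$E %*% x) +
      weights$pos[1L + (t - 1L) * prod(fullTilesWH) + pFull, ]
  }
  attr(tokens, "N") <- N
  attr(tokens, "F") <- Fv
  tokens
}

layerNorm <- function(X, ln) {
  mu <- rowMeans(X)
  sdv <- sqrt(rowMeans((X - mu)^2) + 1e-6)
  sweep(sweep(X, 1, mu), 1, sdv, "/") %*% diag(ln$g) +
    matrix(ln$b, nrow(X), length(ln$b), byrow = TRUE)
}

#' Per-head query/key/value projections
#'
#' q/k/v = W LN(z) for one head: the layer-normalized token is projected
#' by the head's Dh x D matrices.
#'
#' @param tokens token matrix.
#' @param ln layer-norm parameters (list g, b).
#' @param Wq,Wk,Wv Dh x D projection matrices for the head.
#' @return list of M x Dh matrices q, k, v.
#' @export
qkvProject <- function(tokens, ln, Wq, Wk, Wv) {
  Z <- layerNorm(tokens, ln)
  list(q = Z %*% t(Wq), k = Z %*% t(Wk), v = Z %*% t(Wv))
}

softmaxRows <- function(M) {
  mx <- apply(M, 1, max)
  e <- exp(M - mx)
  e / rowSums(e)
}

# shared worker: masked multi-head attention with the divided-attention
# key sets. keySetFor(i) returns the key indices for query token i (NULL
# to pass the token through unchanged).
dividedAttention <- function(tokens, cfg, lnp, Wq, Wk, Wv, Wo, keySetFor) {
  M <- nrow(tokens)
  heads <- vector("list", cfg$A)
  attn <- vector("list", cfg$A)
  for (a in seq_len(cfg$A)) {
    pr <- qkvProject(tokens, lnp, Wq[[a]], Wk[[a]], Wv[[a]])
    out <- matrix(0, M, cfg$Dh)
    aw <- vector("list", M)
    for (i in seq_len(M)) {
      ks <- keySetFor(i)
      if (is.null(ks)) { out[i, ] <- 0; aw[[i]] <- numeric(0); next }
      logits <- as.vector(pr$k[ks, , drop = FALSE] %*% pr$q[i, ]) / sqrt(cfg$Dh)
      w <- exp(logits - max(logits)); w <- w / sum(w)
      out[i, ] <- as.vector(w %*% pr$v[ks, , drop = FALSE])
      aw[[i]] <- w
    }
    heads[[a]] <- out
    attn[[a]] <- aw
  }
  concat <- do.call(cbind, heads)
  delta <- concat %*% t(Wo)
  passthrough <- vapply(seq_len(M), function(i) is.null(keySetFor(i)), TRUE)
  delta[passthrough, ] <- 0
  list(tokens = tokens + delta, attn = attn)
}

#' Depth (temporal) attention
#'
#' For query token (p, t) the keys are the classification token plus the
#' tokens at the same spatial location p in every slice t' = 1..F --
#' exactly F + 1 logits, scaled by 1/sqrt(Dh). The classification token is
#' passed through unchanged (it attends over everything in the spatial
#' step). Heads are concatenated, linearly recombined, and added
#' residually.
#'
#' @param tokens token matrix from [tokenizePatch()] or a previous block.
#' @param cfg an [encoderConfig()].
#' @param block one element of `initEncoder(cfg)$blocks`.
#' @return list(tokens, attn): attn[[head]][[token]] is that query's
#'   weight row over its key set.
#' @export
timeAttention <- function(tokens, cfg, block) {
  N <- attr(tokens, "N"); Fv <- attr(tokens, "F")
  res <- dividedAttention(tokens, cfg, block$lnT, block$WqT, block$WkT,
                          block$WvT, block$WoT, function(i) {
    if (i == 1L) return(NULL)
    p <- (i - 2L) %% N + 1L
    c(1L, tokenIndex(p, seq_len(Fv), N))
  })
  attr(res$tokens, "N") <- N; attr(res$tokens, "F") <- Fv
  res
}

#' Spatial attention
#'
#' For query token (p, t) the keys are the classification token plus all
#' tokens of the same slice t (N + 1 logits). The classification-token
#' query attends over all tokens.
#'
#' @inheritParams timeAttention
#' @return list(tokens, attn) as in [timeAttention()].
#' @export
spaceAttention <- function(tokens, cfg, block) {
  N <- attr(tokens, "N"); Fv <- attr(tokens, "F")
  res <- dividedAttention(tokens, cfg, block$lnS, block$WqS, block$WkS,
                          block$WvS, block$WoS, function(i) {
    if (i == 1L) return(seq_len(N * Fv + 1L))
    t <- (i - 2L) %/% N + 1L
    c(1L, tokenIndex(seq_len(N), t, N))
  })
  attr(res$tokens, "N") <- N; attr(res$tokens, "F") <- Fv
  res
}

gelu <- function(x) x * stats::pnorm(x)

#' One encoder block
#'
#' Depth attention, then spatial attention, then a two-layer GELU MLP of
#' width `mlpRatio * D`, each with a residual connection.
#'
#' @inheritParams timeAttention
#' @return list(tokens, timeAttn, spaceAttn).
#' @export
encoderBlock <- function(tokens, cfg, block) {
  tA <- timeAttention(tokens, cfg, block)
  sA <- spaceAttention(tA$tokens, cfg, block)
  Z <- layerNorm(sA$tokens, block$lnM)
  mlp <- gelu(Z %*% t(block$W1) +
                matrix(block$b1, nrow(Z), length(block$b1), byrow = TRUE)) %*%
    t(block$W2) + matrix(block$b2, nrow(Z), length(block$b2), byrow = TRUE)
  out <- sA$tokens + mlp
  attr(out, "N") <- attr(tokens, "N"); attr(out, "F") <- attr(tokens, "F")
  list(tokens = out, timeAttn = tA$attn, spaceAttn = sA$attn)
}

#' Encode a 2.5D patch
#'
#' Runs tokenization and all L blocks, collecting per-layer attention.
#'
#' @param patch F x H x W x 3 array.
#' @param cfg an [encoderConfig()].
#' @param weights an [initEncoder()] weight set.
#' @param tileOffset,fullTilesWH forwarded to [tokenizePatch()].
#' @return list(tokens, clsEmbedding, attention) where `attention` is a
#'   per-layer list of `timeAttn`/`spaceAttn` head lists.
#' @export
encodePatch <- function(patch, cfg, weights, tileOffset = c(0L, 0L),
                        fullTilesWH = NULL) {
  tokens <- tokenizePatch(patch, cfg, weights, tileOffset, fullTilesWH)
  attention <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    res <- encoderBlock(tokens, cfg, weights$blocks[[l]])
    tokens <- res$tokens
    attention[[l]] <- list(timeAttn = res$timeAttn, spaceAttn = res$spaceAttn)
  }
  list(tokens = tokens, clsEmbedding = tokens[1, ], attention = attention)
}

#' Head-averaged patch-token attention arrays for rollout
#'
#' Converts one layer's stored attention into the head-averaged arrays of
#' Eq-style index form: `T[p, j, q]`, the depth attention of token (p, j)
#' to (p, q), and `S[i, j, p]`, the spatial attention of (i, j) to (p, j).
#' Classification-token keys are dropped and rows renormalized, so both
#' arrays are row-stochastic over their last index.
#'
#' @param layerAttention one element of `encodePatch()$attention`.
#' @param N,F spatial / depth token counts.
#' @return list(S = N x F x N, T = N x F x F arrays).
#' @export
attentionArrays <- function(layerAttention, N, F) {
  A <- length(layerAttention$timeAttn)
  Tarr <- array(0, c(N, F, F))
  Sarr <- array(0, c(N, F, N))
  for (p in seq_len(N)) for (t in seq_len(F)) {
    i <- tokenIndex(p, t, N)
    tw <- Reduce(`+`, lapply(layerAttention$timeAttn, function(h) h[[i]])) / A
    # key set was {cls} U {(p, t'): t' = 1..F}: drop cls, renormalize
    tw <- tw[-1] / sum(tw[-1])
    Tarr[p, t, ] <- tw
    sw <- Reduce(`+`, lapply(layerAttention$spaceAttn, function(h) h[[i]])) / A
    sw <- sw[-1] / sum(sw[-1])
    Sarr[p, t, ] <- sw
  }
  list(S = Sarr, T = Tarr)
}
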
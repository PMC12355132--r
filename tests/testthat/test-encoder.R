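smallCfg <- function(seed = 3, F = 2L, H = 32L, W = 32L, D = 16L, A = 2L,
                     L = 2L, P = 16L) {
  encoderConfig(P = P, D = D, A = A, L = L, F = F, H = H, W = W, seed = seed)
}

randomPatch <- function(cfg, seed = 5) {
  withr::with_seed(seed,
    array(runif(cfg$F * cfg$H * cfg$W * 3, 0, 255),
          c(cfg$F, cfg$H, cfg$W, 3)))
}

test_that("tokenization counts tokens and applies the linear embedding", {
  cfg <- smallCfg()   # H = W = 32, P = 16 -> N = 4; F = 2
  w <- initEncoder(cfg)
  patch <- randomPatch(cfg)
  tokens <- tokenizePatch(patch, cfg, w)
  expect_equal(dim(tokens), c(4 * 2 + 1, cfg$D))
  # zero image with zero positional table: patch tokens are exactly zero
  w0 <- w; w0$pos[] <- 0
  tz <- tokenizePatch(array(0, dim(patch)), cfg, w0)
  expect_true(all(tz[-1, ] == 0))
  # spot-check tokens against manual flatten-then-multiply
  for (pt in list(c(1, 1), c(3, 2), c(4, 1))) {
    p <- pt[1]; t <- pt[2]
    py <- (p - 1) %/% 2 + 1; px <- (p - 1) %% 2 + 1
    tile <- patch[t, ((py - 1) * 16 + 1):(py * 16),
                  ((px - 1) * 16 + 1):(px * 16), ]
    x <- as.vector(aperm(tile, c(2, 1, 3)))
    manual <- as.vector(w$E %*% x) + w$pos[1 + (t - 1) * 4 + p, ]
    expect_equal(tokens[1 + (t - 1) * 4 + p, ], manual, tolerance = 1e-12)
  }
  expect_error(tokenizePatch(array(0, c(2, 30, 32, 3)), cfg, w), "divisible")
})

test_that("qkv projection is W LN(z) per head", {
  cfg <- smallCfg()
  w <- initEncoder(cfg)
  tokens <- tokenizePatch(randomPatch(cfg), cfg, w)
  blk <- w$blocks[[1]]
  pr <- qkvProject(tokens, blk$lnT, blk$WqT[[1]], blk$WkT[[1]], blk$WvT[[1]])
  expect_equal(dim(pr$q), c(nrow(tokens), cfg$Dh))
  # zero weights give zero projections
  zW <- matrix(0, cfg$Dh, cfg$D)
  pr0 <- qkvProject(tokens, blk$lnT, zW, zW, zW)
  expect_true(all(pr0$q == 0) && all(pr0$v == 0))
  # rows already zero-mean unit-variance with unit gain/zero bias:
  # LN is (numerically) the identity, so q equals the plain product
  M <- nrow(tokens)
  Z <- withr::with_seed(8, matrix(rnorm(M * cfg$D), M, cfg$D))
  Z <- (Z - rowMeans(Z)) / sqrt(rowMeans((Z - rowMeans(Z))^2))
  ln1 <- list(g = rep(1, cfg$D), b = rep(0, cfg$D))
  pr1 <- qkvProject(Z, ln1, blk$WqT[[1]], blk$WkT[[1]], blk$WvT[[1]])
  expect_equal(pr1$q, Z %*% t(blk$WqT[[1]]), tolerance = 1e-4)
  # independent dense-layer oracle
  mu <- rowMeans(tokens); sdv <- sqrt(rowMeans((tokens - mu)^2) + 1e-6)
  oracle <- (((tokens - mu) / sdv) %*% diag(blk$lnT$g) +
               matrix(blk$lnT$b, M, cfg$D, byrow = TRUE)) %*% t(blk$WqT[[2]])
  expect_equal(qkvProject(tokens, blk$lnT, blk$WqT[[2]], blk$WkT[[2]],
                          blk$WvT[[2]])$q, oracle, tolerance = 1e-12)
})

test_that("divided attention equals masked full attention", {
  # several seeded configurations, both attention stages
  cases <- list(c(seed = 1, F = 2, H = 32, W = 32),
                c(seed = 2, F = 4, H = 48, W = 16),
                c(seed = 3, F = 3, H = 16, W = 48))
  for (cs in cases) {
    cfg <- smallCfg(seed = cs["seed"], F = as.integer(cs["F"]),
                    H = as.integer(cs["H"]), W = as.integer(cs["W"]))
    w <- initEncoder(cfg)
    blk <- w$blocks[[1]]
    tokens <- tokenizePatch(randomPatch(cfg, seed = cs["seed"] + 10), cfg, w)
    N <- attr(tokens, "N"); Fv <- attr(tokens, "F")
    tA <- timeAttention(tokens, cfg, blk)
    oracleT <- naiveMaskedAttention(tokens, cfg, blk$lnT, blk$WqT, blk$WkT,
                                    blk$WvT, blk$WoT, function(i) {
      if (i == 1L) return(integer(0))
      p <- (i - 2L) %% N + 1L
      c(1L, 1L + (seq_len(Fv) - 1L) * N + p)
    })
    expect_lt(max(abs(tA$tokens - oracleT)), 1e-5)
    sA <- spaceAttention(tA$tokens, cfg, blk)
    oracleS <- naiveMaskedAttention(tA$tokens, cfg, blk$lnS, blk$WqS,
                                    blk$WkS, blk$WvS, blk$WoS, function(i) {
      if (i == 1L) return(seq_len(N * Fv + 1L))
      t <- (i - 2L) %/% N + 1L
      c(1L, 1L + (t - 1L) * N + seq_len(N))
    })
    expect_lt(max(abs(sA$tokens - oracleS)), 1e-5)
    # every attention row sums to 1
    for (h in tA$attn) for (row in h[-1]) expect_lt(abs(sum(row) - 1), 1e-6)
    for (h in sA$attn) for (row in h) expect_lt(abs(sum(row) - 1), 1e-6)
  }
})

test_that("zero logits give uniform attention over the allowed keys", {
  cfg <- smallCfg()
  w <- initEncoder(cfg)
  blk <- w$blocks[[1]]
  # zero q/k weights make all logits zero
  for (a in seq_len(cfg$A)) {
    blk$WqT[[a]][] <- 0; blk$WkT[[a]][] <- 0
    blk$WqS[[a]][] <- 0; blk$WkS[[a]][] <- 0
  }
  tokens <- tokenizePatch(randomPatch(cfg), cfg, w)
  tA <- timeAttention(tokens, cfg, blk)
  expect_equal(tA$attn[[1]][[2]], rep(1 / (cfg$F + 1), cfg$F + 1))
  sA <- spaceAttention(tA$tokens, cfg, blk)
  expect_equal(sA$attn[[1]][[2]], rep(1 / (cfg$N + 1), cfg$N + 1))
})

test_that("an encoder block is time -> space -> MLP with residuals", {
  cfg <- smallCfg()
  w <- initEncoder(cfg)
  tokens <- tokenizePatch(randomPatch(cfg), cfg, w)
  blk <- w$blocks[[1]]
  out <- encoderBlock(tokens, cfg, blk)
  expect_equal(dim(out$tokens), dim(tokens))
  # hand-chained composition gives identical arrays
  tA <- timeAttention(tokens, cfg, blk)
  sA <- spaceAttention(tA$tokens, cfg, blk)
  Z <- sA$tokens
  mu <- rowMeans(Z); sdv <- sqrt(rowMeans((Z - mu)^2) + 1e-6)
  Zn <- ((Z - mu) / sdv) %*% diag(blk$lnM$g) +
    matrix(blk$lnM$b, nrow(Z), cfg$D, byrow = TRUE)
  act <- Zn %*% t(blk$W1) + matrix(blk$b1, nrow(Z), length(blk$b1), byrow = TRUE)
  mlp <- (act * pnorm(act)) %*% t(blk$W2) +
    matrix(blk$b2, nrow(Z), cfg$D, byrow = TRUE)
  expect_equal(unclass(out$tokens), unclass(Z + mlp), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zeroed output/MLP weights with residuals: identity block
  blk0 <- blk
  blk0$WoT[] <- 0; blk0$WoS[] <- 0; blk0$W2[] <- 0; blk0$b2[] <- 0
  out0 <- encoderBlock(tokens, cfg, blk0)
  expect_equal(unclass(out0$tokens), unclass(tokens), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("depth permutation permutes outputs and spares the class token", {
  cfg <- smallCfg(F = 3L)
  w <- initEncoder(cfg)
  patch <- randomPatch(cfg)
  perm <- c(3L, 1L, 2L)
  patchP <- patch[perm, , , , drop = FALSE]
  # permute the temporal positional rows identically
  wP <- w
  N <- cfg$N
  for (t in seq_len(cfg$F)) {
    wP$pos[1 + (t - 1) * N + seq_len(N), ] <-
      w$pos[1 + (perm[t] - 1) * N + seq_len(N), ]
  }
  e1 <- encodePatch(patch, cfg, w)
  e2 <- encodePatch(patchP, cfg, wP)
  for (t in seq_len(cfg$F)) {
    rows1 <- 1 + (perm[t] - 1) * N + seq_len(N)
    rows2 <- 1 + (t - 1) * N + seq_len(N)
    expect_equal(e2$tokens[rows2, ], e1$tokens[rows1, ], tolerance = 1e-8)
  }
  expect_equal(e2$clsEmbedding, e1$clsEmbedding, tolerance = 1e-8)
})

test_that("parameter count is a pure function of the configuration", {
  countParams <- function(x) {
    if (is.list(x)) return(sum(vapply(x, countParams, 1)))
    length(x)
  }
  cfg <- smallCfg()
  n1 <- countParams(initEncoder(cfg))
  n2 <- countParams(initEncoder(smallCfg(seed = 99)))
  expect_identical(n1, n2)
  # regression against the closed-form count
  D <- cfg$D; A <- cfg$A; Dh <- cfg$Dh; L <- cfg$L
  Dm <- round(cfg$mlpRatio * D)
  perBlock <- 2 * (2 * D + 3 * A * Dh * D + D * D) + 2 * D +
    Dm * D + Dm + D * Dm + D
  expected <- D * 3 * cfg$P^2 + (cfg$N * cfg$F + 1) * D + D + L * perBlock
  expect_identical(n1, as.numeric(expected))
})
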
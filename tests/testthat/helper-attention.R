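# Independent oracle: naive full attention over all tokens with an
# explicit key mask, coded separately from the package's divided path.
naiveMaskedAttention <- function(tokens, cfg, ln, Wq, Wk, Wv, Wo, maskFor) {
  M <- nrow(tokens)
  mu <- rowMeans(tokens)
  sdv <- sqrt(rowMeans((tokens - mu)^2) + 1e-6)
  Z <- ((tokens - mu) / sdv) %*% diag(ln$g) +
    matrix(ln$b, M, length(ln$b), byrow = TRUE)
  heads <- list()
  for (a in seq_along(Wq)) {
    q <- Z %*% t(Wq[[a]]); k <- Z %*% t(Wk[[a]]); v <- Z %*% t(Wv[[a]])
    logits <- q %*% t(k) / sqrt(cfg$Dh)
    out <- matrix(0, M, cfg$Dh)
    for (i in seq_len(M)) {
      allowed <- maskFor(i)
      if (length(allowed) == 0L) next
      l <- logits[i, allowed]
      w <- exp(l - max(l)); w <- w / sum(w)
      out[i, ] <- as.vector(w %*% v[allowed, , drop = FALSE])
    }
    heads[[a]] <- out
  }
  delta <- do.call(cbind, heads) %*% t(Wo)
  skip <- vapply(seq_len(M), function(i) length(maskFor(i)) == 0L, TRUE)
  delta[skip, ] <- 0
  tokens + delta
}
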
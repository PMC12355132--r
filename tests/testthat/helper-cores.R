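# synthetic cores for the patch-extraction checks
fullTissueCore <- function(L = 512, Z = 4) {
  secs <- lapply(seq_len(Z), function(k)
    SectionImage(array(180, c(L, L, 3)), mpp = 0.5))
  masks <- lapply(seq_len(Z), function(k) TissueMask(matrix(1, L, L)))
  assembleCore(secs, masks, 0.5)
}

randomMaskCore <- function(L, Z, seed, pTissue = 0.55) {
  withr::with_seed(seed, {
    secs <- lapply(seq_len(Z), function(k)
      SectionImage(array(128, c(L, L, 3)), mpp = 0.5))
    masks <- lapply(seq_len(Z), function(k) {
      coarse <- matrix(runif(64), 8, 8) < pTissue
      TissueMask(matrix(as.numeric(coarse[cbind(
        rep(ceiling(seq_len(L) / (L / 8)), L),
        rep(ceiling(seq_len(L) / (L / 8)), each = L))]), L, L))
    })
    assembleCore(secs, masks, 0.5)
  })
}

# brute-force patch enumeration, independent of extractPatches
bruteForcePatches <- function(core, patchPx, minFraction) {
  reg <- buildRegistrationMask(core@masks)
  bb <- reg$bbox
  out <- list()
  if (bb[3] - bb[1] < patchPx || bb[4] - bb[2] < patchPx) return(out)
  for (y0 in seq(bb[2], bb[4] - patchPx, by = patchPx))
    for (x0 in seq(bb[1], bb[3] - patchPx, by = patchPx)) {
      fr <- mean(vapply(core@masks, function(m)
        mean(maskData(m)[(y0 + 1):(y0 + patchPx), (x0 + 1):(x0 + patchPx)]), 1))
      if (fr > minFraction) out[[length(out) + 1L]] <- c(x0, y0, fr)
    }
  out
}
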
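test_that("core assembly validates shapes and preserves depth", {
  core <- fullTissueCore(128, 8)
  expect_equal(coreDepth(core), 8)
  bad <- lapply(1:3, function(k)
    SectionImage(array(0, c(64 + (k == 2) * 8, 64, 3))))
  expect_error(assembleCore(bad, lapply(1:3, function(k)
    TissueMask(matrix(1, 64, 64))), 0.5), "section 2")
  expect_error(assembleCore(list(SectionImage(array(0, c(8, 8, 3)))),
                            list(TissueMask(matrix(1, 8, 8))), 0.5),
               "at least 2")
})

test_that("patch tissue fraction averages the per-section in-window fractions", {
  core <- fullTissueCore(512, 4)
  expect_equal(patchTissueFraction(core, c(0, 0)), 1)
  # half tissue in every section
  L <- 512
  half <- lapply(1:4, function(k) {
    m <- matrix(0, L, L); m[, 1:(L / 2)] <- 1; TissueMask(m)
  })
  coreH <- assembleCore(core@volume, half, 0.5)
  expect_equal(patchTissueFraction(coreH, c(128, 0)), 0.5)
  # random masks: equals the brute-force pixel count
  coreR <- randomMaskCore(512, 3, seed = 21)
  fr <- patchTissueFraction(coreR, c(64, 128))
  manual <- mean(vapply(coreR@masks, function(m)
    sum(maskData(m)[129:384, 65:320]), 1)) / 256^2
  expect_equal(fr, manual)
  expect_error(patchTissueFraction(core, c(400, 0)), "outside")
})

test_that("patch extraction tiles the bbox grid with a strict 60% rule", {
  core <- fullTissueCore(512, 4)
  patches <- extractPatches(core)
  expect_length(patches, 4)
  for (p in patches) {
    expect_equal(dim(p@data), c(4, 256, 256, 3))
    expect_equal(p@tissueFraction, 1)
    expect_true(all(p@origin %% 256 == 0))
  }
  # a window at exactly the threshold fraction is excluded ("more than 60%")
  # (patch 100 px so 0.6 * 100^2 is attainable exactly; corner pixels pin
  # the tissue bounding box to the full window)
  L <- 100
  m <- matrix(0, L, L)
  m[1:60, 1:100] <- 1          # 6000 px
  m[60, 100] <- 0; m[100, 100] <- 1   # keep 6000 px, bbox = full canvas
  expect_equal(sum(m), 0.6 * L^2)
  coreB <- assembleCore(lapply(1:2, function(k)
    SectionImage(array(0, c(L, L, 3)))), list(TissueMask(m), TissueMask(m)), 0.5)
  expect_length(extractPatches(coreB, patchPx = 100), 0)
  mAbove <- m; mAbove[61, 1] <- 1     # 6001 px: fraction 0.6001 > 0.6
  coreC <- assembleCore(coreB@volume,
                        list(TissueMask(mAbove), TissueMask(mAbove)), 0.5)
  expect_length(extractPatches(coreC, patchPx = 100), 1)
  # a core smaller than the patch yields no patches, not an error
  tiny <- fullTissueCore(128, 2)
  expect_length(extractPatches(tiny, patchPx = 256), 0)
})

test_that("kept patches equal brute-force enumeration over all grid origins", {
  for (seed in c(31, 32, 33)) {
    core <- randomMaskCore(512, 3, seed = seed)
    patches <- extractPatches(core, patchPx = 128, minFraction = 0.6)
    reg <- buildRegistrationMask(core@masks)
    bb <- reg$bbox
    expected <- list()
    ys <- seq(bb[2], bb[4] - 128, by = 128)
    xs <- seq(bb[1], bb[3] - 128, by = 128)
    for (y0 in ys) for (x0 in xs) {
      fr <- mean(vapply(core@masks, function(m)
        mean(maskData(m)[(y0 + 1):(y0 + 128), (x0 + 1):(x0 + 128)]), 1))
      if (fr > 0.6) expected[[length(expected) + 1L]] <- c(x0, y0, fr)
    }
    expect_equal(length(patches), length(expected))
    for (i in seq_along(patches)) {
      expect_equal(patches[[i]]@origin, expected[[i]][1:2])
      expect_equal(patches[[i]]@tissueFraction, expected[[i]][3])
      expect_gt(patches[[i]]@tissueFraction, 0.6)
    }
    # tiling invariant: pairwise disjoint origins on the stride grid
    if (length(patches) > 1) {
      org <- t(vapply(patches, function(p) p@origin, numeric(2)))
      expect_false(any(duplicated(org)))
    }
  }
})

test_that("registration error statistics follow their definitions", {
  # coincident points: zero error
  pts <- cbind(c(1, 5, 9), c(2, 4, 8))
  pe <- pairRegistrationError(pts, pts, mpp = 0.5)
  expect_equal(pe$medianUm, 0)
  expect_equal(pe$nMatches, 3)
  # median of {0.5, 1.0, 4.5} um is 1.0
  a <- cbind(c(0, 0, 0), c(0, 0, 0))
  b <- cbind(c(1, 2, 9), c(0, 0, 0))
  expect_equal(pairRegistrationError(a, b, mpp = 0.5)$medianUm, 1.0)
  # 1000 random pairs against a sort-based median oracle
  withr::with_seed(8, {
    pa <- matrix(runif(2000, 0, 100), 1000, 2)
    pb <- pa + matrix(rnorm(2000), 1000, 2)
    d <- sqrt(rowSums((pa - pb)^2)) * 0.7
    ds <- sort(d)
    oracle <- (ds[500] + ds[501]) / 2
    expect_equal(pairRegistrationError(pa, pb, 0.7)$medianUm, oracle)
  })
  expect_error(pairRegistrationError(matrix(0, 0, 2), matrix(0, 0, 2), 1),
               "no matched")
  # weighted core error: (2 * 10 + 4 * 30) / 40 = 3.5
  rep1 <- data.frame(pair = 1:2, median_um = c(2, 4), n_matches = c(10, 30))
  expect_equal(coreRegistrationError(rep1), 3.5)
  rep2 <- data.frame(pair = 1:3, median_um = c(1, 2, 6), n_matches = rep(7, 3))
  expect_equal(coreRegistrationError(rep2), 3)   # equal weights: plain mean
  # random report vs independent accumulation
  withr::with_seed(9, {
    r <- data.frame(pair = 1:20, median_um = runif(20, 0, 50),
                    n_matches = sample(1:100, 20))
    acc <- 0; wsum <- 0
    for (i in 1:20) { acc <- acc + r$median_um[i] * r$n_matches[i]
                      wsum <- wsum + r$n_matches[i] }
    expect_equal(coreRegistrationError(r), acc / wsum)
  })
  expect_error(coreRegistrationError(data.frame(pair = 1, median_um = 2,
                                                n_matches = 0)), "zero")
})

test_that("identical stacks score near-zero core error", {
  ph <- testPhantom(seed = 7, nSections = 4, warpAmplitude = 0)
  s <- ph@sections[[1]]
  rep0 <- stackRegistrationError(list(s, s, s), mpp = 0.5)
  expect_lt(coreError(rep0), 0.5)
})
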
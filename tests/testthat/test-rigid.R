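test_that("keypoint detection is deterministic and respects its contracts", {
  flat <- SectionImage(array(128, c(64, 64, 3)))
  expect_equal(nKeypoints(detectKeypoints(flat)), 0)
  ph <- testPhantom(seed = 7, nSections = 4, warpAmplitude = 0)
  kp <- detectKeypoints(ph@sections[[1]])
  expect_gt(nKeypoints(kp), 50)
  kp2 <- detectKeypoints(ph@sections[[1]])
  expect_identical(kp@positions, kp2@positions)
  expect_identical(kp@descriptors, kp2@descriptors)
  # mask restriction
  mask <- computeTissueMask(ph@sections[[1]])
  kpM <- detectKeypoints(ph@sections[[1]], mask = mask)
  inMask <- maskData(mask)[cbind(kpM@positions[, 2] + 1, kpM@positions[, 1] + 1)]
  expect_true(all(inMask > 0))
  # cap respected
  expect_lte(nKeypoints(detectKeypoints(ph@sections[[1]], maxKeypoints = 20L)), 20)
})

test_that("matching recovers identity and permutations, and the ratio test filters", {
  ph <- testPhantom(seed = 7, nSections = 4, warpAmplitude = 0)
  kp <- detectKeypoints(ph@sections[[1]], maxKeypoints = 100L)
  m <- matchKeypoints(kp, kp)
  expect_equal(nrow(m@pairs), nKeypoints(kp))
  expect_equal(m@pairs[, 1], m@pairs[, 2])
  # permuted copy: brute-force nearest neighbour is the ground truth
  perm <- withr::with_seed(2, sample(nKeypoints(kp)))
  kpP <- new("KeypointSet", positions = kp@positions[perm, ],
             descriptors = kp@descriptors[perm, ], scores = kp@scores[perm],
             orientations = kp@orientations[perm])
  mp <- matchKeypoints(kp, kpP)
  expect_equal(nrow(mp@pairs), nKeypoints(kp))
  expect_equal(perm[mp@pairs[, 2]], mp@pairs[, 1])
  # two equidistant neighbours fail a 0.75 ratio test
  da <- matrix(c(1, 0, 0, 0), 1, 4)
  db <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0))   # equidistant from da
  a <- new("KeypointSet", positions = cbind(30, 30), descriptors = da,
           scores = 1, orientations = 0)
  b <- new("KeypointSet", positions = cbind(c(30, 40), c(30, 40)),
           descriptors = db, scores = c(1, 1), orientations = c(0, 0))
  expect_equal(nrow(matchKeypoints(a, b, ratio = 0.75)@pairs), 0)
  # empty input gives an empty match set
  empty <- new("KeypointSet", positions = matrix(0, 0, 2),
               descriptors = matrix(0, 0, 128), scores = numeric(0),
               orientations = numeric(0))
  expect_equal(nrow(matchKeypoints(empty, kp)@pairs), 0)
})

syntheticMatches <- function(n, t, noiseSd = 0, seed = 1) {
  withr::with_seed(seed, {
    P <- cbind(runif(n, 0, 200), runif(n, 0, 200))
    Q <- transformPoints(P, t) + matrix(rnorm(2 * n, sd = noiseSd), n, 2)
    a <- new("KeypointSet", positions = P, descriptors = diag(n),
             scores = rep(1, n), orientations = rep(0, n))
    b <- new("KeypointSet", positions = Q, descriptors = diag(n),
             scores = rep(1, n), orientations = rep(0, n))
    m <- new("MatchSet", pairs = cbind(1:n, 1:n), distances = rep(0, n),
             inlierFlags = rep(TRUE, n))
    list(a = a, b = b, m = m)
  })
}

test_that("similarity estimation recovers exact and contaminated transforms", {
  # identical points: identity within 1e-9
  s <- syntheticMatches(20, identityTransform(), seed = 4)
  fit <- estimateSimilarity(s$m, s$a, s$b, seed = 1)
  expect_lt(abs(fit@theta), 1e-9)
  expect_lt(abs(fit@scale - 1), 1e-9)
  expect_lt(max(abs(c(fit@tx, fit@ty))), 1e-9)
  # noiseless known transform: machine precision
  t1 <- similarityTransform(theta = 10 * pi / 180, scale = 1.02, tx = 5, ty = -3)
  s <- syntheticMatches(30, t1, seed = 5)
  fit <- estimateSimilarity(s$m, s$a, s$b, seed = 1)
  expect_lt(abs(fit@theta - t1@theta), 1e-10)
  expect_lt(abs(fit@scale - t1@scale), 1e-10)
  expect_lt(max(abs(c(fit@tx - t1@tx, fit@ty - t1@ty))), 1e-7)
  # 20% gross outliers: consensus loop rejects them
  s <- syntheticMatches(50, t1, noiseSd = 0.1, seed = 6)
  bad <- 1:10
  s$b@positions[bad, ] <- s$b@positions[bad, ] +
    withr::with_seed(7, matrix(runif(20, 40, 80), 10, 2))
  fit <- estimateSimilarity(s$m, s$a, s$b, seed = 2)
  expect_lt(abs(fit@theta - t1@theta) * 180 / pi, 0.5)
  expect_lt(abs(fit@scale - t1@scale), 0.01)
  expect_lt(max(abs(c(fit@tx - t1@tx, fit@ty - t1@ty))), 1)
  expect_false(any(attr(fit, "inlierFlags")[bad]))
  # determinism given seed
  fit2 <- estimateSimilarity(s$m, s$a, s$b, seed = 2)
  expect_identical(fit@theta, fit2@theta)
  # failure modes
  expect_error(estimateSimilarity(new("MatchSet", pairs = cbind(1:2, 1:2),
                                      distances = rep(0, 2),
                                      inlierFlags = rep(TRUE, 2)),
                                  s$a, s$b), "insufficient")
  coincident <- syntheticMatches(5, t1, seed = 8)
  coincident$a@positions[] <- 10
  coincident$b@positions[] <- 12
  expect_error(estimateSimilarity(coincident$m, coincident$a, coincident$b),
               "degenerate")
})

test_that("no reflection can be produced by the similarity fit", {
  # even when correspondences come from a reflection, the fitted linear
  # part keeps determinant scale^2 > 0
  P <- withr::with_seed(9, matrix(runif(40, 0, 100), 20, 2))
  Q <- cbind(-P[, 1], P[, 2])   # mirrored
  a <- new("KeypointSet", positions = P, descriptors = diag(20),
           scores = rep(1, 20), orientations = rep(0, 20))
  b <- new("KeypointSet", positions = Q, descriptors = diag(20),
           scores = rep(1, 20), orientations = rep(0, 20))
  m <- new("MatchSet", pairs = cbind(1:20, 1:20), distances = rep(0, 20),
           inlierFlags = rep(TRUE, 20))
  fit <- estimateSimilarity(m, a, b, inlierTolPx = 1e6, seed = 1)
  expect_gt(fit@scale, 0)
})

test_that("transform algebra: rescaling, inversion, composition", {
  t1 <- similarityTransform(theta = 0.2, scale = 1.05, tx = 3, ty = 4,
                            levelMpp = 2)
  r <- rescaleTransform(t1, 8)
  expect_equal(c(r@tx, r@ty), c(24, 32))
  expect_equal(r@theta, t1@theta)
  expect_equal(r@scale, t1@scale)
  expect_equal(r@levelMpp, 0.25)
  expect_equal(rescaleTransform(t1, 1), t1)
  rt <- rescaleTransform(rescaleTransform(t1, 8), 1 / 8)
  expect_equal(c(rt@tx, rt@ty, rt@theta, rt@scale),
               c(t1@tx, t1@ty, t1@theta, t1@scale))
  expect_error(rescaleTransform(t1, 0), "factor")
  # composition of two similarities is a similarity: angles add, scales
  # multiply, and probe points agree with sequential application
  t2 <- similarityTransform(theta = -0.1, scale = 0.97, tx = -5, ty = 2)
  comp <- composeTransforms(t2, t1)
  expect_equal(comp@theta, t1@theta + t2@theta)
  expect_equal(comp@scale, t1@scale * t2@scale)
  probes <- withr::with_seed(1, matrix(rnorm(20, sd = 30), 10, 2))
  expect_equal(transformPoints(probes, comp),
               transformPoints(transformPoints(probes, t1), t2),
               tolerance = 1e-12)
  # inversion round trip
  inv <- invertTransform(t1)
  expect_equal(transformPoints(transformPoints(probes, t1), inv), probes,
               tolerance = 1e-10)
})

test_that("similarity warping follows the backward-mapping convention", {
  ph <- testPhantom(seed = 7, nSections = 4, warpAmplitude = 0)
  img <- ph@sections[[1]]
  expect_identical(warpSimilarity(img, identityTransform())@data, img@data)
  # warp by t then t^{-1} returns close to the original in the interior
  # (smooth image: the bound reflects interpolation error, not speckle)
  t1 <- similarityTransform(theta = 0.1, scale = 1.01, tx = 4, ty = -6)
  gx <- outer(seq_len(128), seq_len(128), function(i, j)
    127 + 100 * sin(i / 9) * cos(j / 13))
  smooth <- SectionImage(array(rep(gx, 3), c(128, 128, 3)))
  rt <- warpSimilarity(warpSimilarity(smooth, t1), invertTransform(t1))
  interior <- 20:108
  expect_lt(mean(abs(rt@data[interior, interior, 1] -
                     smooth@data[interior, interior, 1])), 2)
  # a single dark pixel lands at transformPoints(p, t)
  one <- SectionImage(array(255, c(64, 64, 3)))
  one@data[31, 21, ] <- 0
  w <- warpSimilarity(one, t1)
  idx <- which(w@data[, , 1] == min(w@data[, , 1]), arr.ind = TRUE)
  pred <- transformPoints(cbind(20, 30), t1)
  expect_lt(max(abs(c(idx[1, 2] - 1, idx[1, 1] - 1) - pred)), 1)
})

test_that("serial registration recovers the phantom chain", {
  # identical sections: identity within tight tolerances
  ph0 <- testPhantom(seed = 7, nSections = 4, warpAmplitude = 0)
  same <- list(ph0@sections[[1]], ph0@sections[[1]], ph0@sections[[1]])
  tr0 <- registerStackSerial(same, seed = 3)
  for (k in 2:3) {
    expect_lt(abs(tr0[[k]]@theta) * 180 / pi, 0.05)
    expect_lt(abs(tr0[[k]]@scale - 1), 0.001)
    expect_lt(max(abs(c(tr0[[k]]@tx, tr0[[k]]@ty))), 0.1)
  }
  # corrupted phantom: ground-truth chain recovered
  ph <- testPhantom(seed = 7, nSections = 4, warpAmplitude = 0)
  masks <- testMasks(ph)
  tr <- registerStackSerial(ph@sections, masks, seed = 5)
  ok <- vapply(2:4, function(k)
    transformClose(tr[[k]], ph@trueTransforms[[k]]), TRUE)
  expect_true(all(ok))
  # determinism: bit-identical transforms on a rerun with the same seed
  tr2 <- registerStackSerial(ph@sections, masks, seed = 5)
  for (k in 1:4) {
    expect_identical(tr[[k]]@theta, tr2[[k]]@theta)
    expect_identical(tr[[k]]@tx, tr2[[k]]@tx)
  }
  # serial recovery drops the median landmark distance to the reference
  before <- after <- c()
  for (k in 2:4) {
    before <- c(before, sqrt(rowSums((ph@landmarks[[k]] - ph@landmarks[[1]])^2)))
    aligned <- transformPoints(ph@landmarks[[k]], tr[[k]])
    after <- c(after, sqrt(rowSums((aligned - ph@landmarks[[1]])^2)))
  }
  expect_gte(median(before), 10)
  expect_lte(median(after), 2)
})

test_that("chained pairwise fits compose to the serial transform on probes", {
  ph <- testPhantom(seed = 7, nSections = 4, warpAmplitude = 0)
  masks <- testMasks(ph)
  tr <- registerStackSerial(ph@sections, masks, seed = 5)
  # independent pairwise fits between raw neighbours
  pairFit <- function(i, j) {
    kpi <- detectKeypoints(ph@sections[[i]], mask = masks[[i]])
    kpj <- detectKeypoints(ph@sections[[j]], mask = masks[[j]])
    m <- matchKeypoints(kpi, kpj)
    estimateSimilarity(m, kpi, kpj, seed = 11)
  }
  p21 <- pairFit(2, 1)
  p32 <- pairFit(3, 2)
  comp <- composeTransforms(p21, p32)   # section 3 -> 1 via 2
  probes <- withr::with_seed(2, matrix(runif(20, 100, 280), 10, 2))
  expect_lt(max(abs(transformPoints(probes, comp) -
                    transformPoints(probes, tr[[3]]))), 1.5)
})
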
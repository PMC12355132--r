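test_that("gated attention pooling satisfies its structural contracts", {
  params <- abmilInit(D = 6, nClasses = 3, hidden = 8, seed = 2)
  # singleton bag: attention weight exactly 1
  one <- featureBag(matrix(rnorm(6), 1, 6))
  out1 <- abmilPool(one, params)
  expect_identical(out1$attention, 1)
  expect_equal(sum(out1$classProbs), 1, tolerance = 1e-9)
  # identical instances: uniform weights 1/K
  same <- featureBag(matrix(rep(rnorm(6), each = 5), 5, 6))
  expect_equal(abmilPool(same, params)$attention, rep(0.2, 5))
  # permutation invariance: weights permute, probabilities unchanged
  H <- withr::with_seed(3, matrix(rnorm(48), 8, 6))
  perm <- withr::with_seed(4, sample(8))
  a <- abmilPool(featureBag(H), params)
  b <- abmilPool(featureBag(H[perm, ]), params)
  expect_equal(b$attention, a$attention[perm], tolerance = 1e-12)
  expect_equal(b$classProbs, a$classProbs, tolerance = 1e-12)
  # weighted feature sum matches a manual dot-product oracle
  hv <- tanh(H %*% t(params$V)); hu <- 1 / (1 + exp(-(H %*% t(params$U))))
  sc <- as.vector((hv * hu) %*% params$w)
  wts <- exp(sc - max(sc)); wts <- wts / sum(wts)
  z <- colSums(H * wts)
  logits <- as.vector(params$C %*% z) + params$b
  expect_equal(a$logits, logits, tolerance = 1e-12)
})

test_that("the analytic ABMIL gradient matches finite differences", {
  params <- abmilInit(D = 5, nClasses = 2, hidden = 6, seed = 7)
  bag <- featureBag(withr::with_seed(8, matrix(rnorm(20), 4, 5)))
  gr <- HistoStack:::abmilGrad(bag, params, label = 2)
  lossAt <- function(p) -log(abmilPool(bag, p)$classProbs[2])
  for (nm in c("V", "U", "C")) {
    idx <- c(2, 3)
    eps <- 1e-6
    up <- params; up[[nm]][idx[1], idx[2]] <- up[[nm]][idx[1], idx[2]] + eps
    dn <- params; dn[[nm]][idx[1], idx[2]] <- dn[[nm]][idx[1], idx[2]] - eps
    num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
    expect_equal(gr[[nm]][idx[1], idx[2]], num, tolerance = 1e-5)
  }
  up <- params; up$w[3] <- up$w[3] + 1e-6
  dn <- params; dn$w[3] <- dn$w[3] - 1e-6
  expect_equal(gr$w[3], (lossAt(up) - lossAt(dn)) / 2e-6, tolerance = 1e-5)
})

test_that("a trained ABMIL solves the separable bag task and localizes signal", {
  data <- syntheticBags(seed = 7)
  fit <- trainAbmil(data$bags[data$train], data$labels[data$train],
                    nClasses = 2, hidden = 32, epochs = 150, lr = 1, seed = 7)
  test <- which(!data$train)
  probs <- t(vapply(data$bags[test], function(b)
    abmilPool(b, fit$params)$classProbs, numeric(2)))
  ev <- evaluateMulticlass(probs, data$labels[test], levels = c("neg", "pos"))
  expect_gte(ev$metrics$auc, 0.9)
  posTest <- test[data$labels[test] == 2]
  hits <- vapply(posTest, function(i) {
    at <- abmilPool(data$bags[[i]], fit$params)$attention
    which.max(at) %in% data$signalIndex[[i]]
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("grade groups binarize at the clinical-significance threshold", {
  expect_false(binarizeCS("GG1"))
  expect_true(binarizeCS("GG2"))
  expect_false(binarizeCS("BN"))
  expect_equal(binarizeCS(c("BN", "GG1", "GG2", "GG3", "GG4/5")),
               c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(binarizeCS("GG6"), "unknown")
})

test_that("multi-class metrics match hand computation and a null simulation", {
  # perfect predictions: everything 1, identity confusion
  probs <- diag(3)[c(1, 2, 3, 1, 2, 3), ]
  ev <- evaluateMulticlass(probs, c(1, 2, 3, 1, 2, 3))
  expect_equal(ev$metrics$auc, 1)
  expect_equal(ev$metrics$f1, 1)
  expect_true(all(diag(ev$confusionNorm) == 1))
  # printed 3-class toy: confusion counts worked through by hand
  #   truth 1: 8 as 1, 2 as 2;  truth 2: 3 as 1, 6 as 2, 1 as 3;
  #   truth 3: 0 as 1, 2 as 2, 8 as 3
  labels <- rep(1:3, c(10, 10, 10))
  pred <- c(rep(1, 8), rep(2, 2), rep(1, 3), rep(2, 6), 3, rep(2, 2), rep(3, 8))
  probsT <- diag(3)[pred, ] * 0.9 + 0.05
  evT <- evaluateMulticlass(probsT, labels)
  # per-class: P1 = 8/11, R1 = 8/10, F1_1 = 16/21
  #            P2 = 6/10, R2 = 6/10, F1_2 = 3/5
  #            P3 = 8/9,  R3 = 8/10, F1_3 = 16/19
  f1Hand <- mean(c(2 * (8/11) * (8/10) / (8/11 + 8/10),
                   0.6,
                   2 * (8/9) * (8/10) / (8/9 + 8/10)))
  expect_equal(evT$metrics$f1, f1Hand, tolerance = 1e-12)
  expect_equal(evT$confusion[2, 1], 3)
  # shuffled labels: AUC near 1/2
  withr::with_seed(10, {
    n <- 10000
    p <- matrix(runif(2 * n), n, 2); p <- p / rowSums(p)
    lab <- sample(1:2, n, replace = TRUE)
    evN <- evaluateMulticlass(p, lab)
    expect_lt(abs(evN$metrics$auc - 0.5), 0.02)
  })
  expect_error(evaluateMulticlass(probs, rep(1, 6)), "single class")
})

test_that("McNemar's statistic follows the discordant-count formula", {
  a <- c(TRUE, TRUE, FALSE, TRUE); b <- c(TRUE, FALSE, TRUE, FALSE)
  # b (A right, B wrong) = 2, c = 1 -> (2-1)^2 / 3
  r <- mcnemarChi2(a, b)
  expect_equal(r$statistic, 1 / 3)
  # b = c gives 0
  expect_equal(mcnemarChi2(c(TRUE, FALSE), c(FALSE, TRUE))$statistic, 0)
  # b = 10, c = 0 gives 10
  expect_equal(mcnemarChi2(rep(TRUE, 10), rep(FALSE, 10))$statistic, 10)
  # random paired outcomes: cross-check against stats::mcnemar.test
  withr::with_seed(11, {
    ca <- runif(200) < 0.7; cb <- runif(200) < 0.6
    mine <- mcnemarChi2(ca, cb)
    ref <- stats::mcnemar.test(table(ca, cb), correct = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$pValue, unname(ref$p.value))
  })
  expect_error(mcnemarChi2(c(TRUE, FALSE), c(TRUE, FALSE)), "undefined")
})

test_that("quadratic-weighted kappa matches its O/E definition", {
  expect_equal(quadraticWeightedKappa(c(1, 2, 3, 2), c(1, 2, 3, 2)), 1)
  # 3-category toy table worked through by hand:
  # ratings A = (1,1,2,3), B = (1,2,2,3)
  a <- c(1, 1, 2, 3); b <- c(1, 2, 2, 3)
  O <- matrix(0, 3, 3)
  for (k in 1:4) O[a[k], b[k]] <- O[a[k], b[k]] + 1 / 4
  E <- outer(rowSums(O), colSums(O))
  W <- outer(1:3, 1:3, function(i, j) (i - j)^2) / 4
  expect_equal(quadraticWeightedKappa(a, b, categories = 1:3),
               1 - sum(W * O) / sum(W * E), tolerance = 1e-12)
  # independent uniform ratings: kappa near zero
  withr::with_seed(12, {
    ra <- sample(1:5, 1e5, replace = TRUE)
    rb <- sample(1:5, 1e5, replace = TRUE)
    expect_lt(abs(quadraticWeightedKappa(ra, rb, categories = 1:5)), 0.02)
  })
  expect_error(quadraticWeightedKappa(integer(0), integer(0)), "empty")
})
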
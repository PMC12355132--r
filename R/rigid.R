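# Keypoint-based serial similarity registration.
#
# Detector: Harris corners with an orientation-normalized 4x4x8
# gradient-histogram descriptor (the SIFT family's design, implemented
# deterministically). Matcher: mutual nearest neighbour + Lowe ratio,
# one-to-one by construction, behind the same contract a learned
# optimal-transport matcher would satisfy. Fit: closed-form least-squares
# similarity (rotation + isotropic scale + translation only; reflection
# impossible by construction) inside a seeded random-sample consensus loop.

DESC_GRID <- 18L     # descriptor sampling grid (gradients on the inner 16x16)
DESC_SPACING <- 1.5  # px between descriptor samples (support ~26 px)
DESC_MARGIN <- 20    # border margin so every rotated sample stays inside

#' Detect oriented keypoints with descriptors
#'
#' Harris corner responses on the blurred luminance image, 3x3 non-maximum
#' suppression, strongest `maxKeypoints` kept (stable ordering: response,
#' then y, then x). Each keypoint gets a dominant gradient orientation and
#' a 128-d orientation-normalized gradient-histogram descriptor, so
#' matching tolerates the rotations and small scale changes seen between
#' serial sections. Fully deterministic for a fixed image.
#'
#' @param img a [SectionImage-class].
#' @param maxKeypoints cap on the number of keypoints returned.
#' @param mask optional [TissueMask-class]; detection is restricted to it.
#' @return a [KeypointSet-class] (empty on a blank image).
#' @export
detectKeypoints <- function(img, maxKeypoints = 500L, mask = NULL) {
  gray <- (img@data[, , 1] + img@data[, , 2] + img@data[, , 3]) / (3 * 255)
  H <- nrow(gray); W <- ncol(gray)
  g <- gaussianBlur(gray, 1)
  gr <- imageGradients(g)
  Sxx <- gaussianBlur(gr$gx^2, 2)
  Syy <- gaussianBlur(gr$gy^2, 2)
  Sxy <- gaussianBlur(gr$gx * gr$gy, 2)
  R <- Sxx * Syy - Sxy^2 - 0.05 * (Sxx + Syy)^2
  mx <- max(R)
  emptySet <- new("KeypointSet", positions = matrix(0, 0, 2),
                  descriptors = matrix(0, 0, 128L), scores = numeric(0),
                  orientations = numeric(0))
  if (mx <= 1e-12) return(emptySet)
  localMax <- maxFilter3(R)
  cand <- which(R >= localMax - 1e-15 & R > 1e-4 * mx, arr.ind = TRUE)
  keep <- cand[, 1] > DESC_MARGIN & cand[, 1] <= H - DESC_MARGIN &
          cand[, 2] > DESC_MARGIN & cand[, 2] <= W - DESC_MARGIN
  cand <- cand[keep, , drop = FALSE]
  if (!is.null(mask)) {
    inMask <- maskData(mask)[cand] > 0
    cand <- cand[inMask, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(emptySet)
  resp <- R[cand]
  ord <- order(-resp, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  resp <- resp[ord]
  n <- min(nrow(cand), maxKeypoints)
  cand <- cand[seq_len(n), , drop = FALSE]
  resp <- resp[seq_len(n)]
  px <- cand[, 2] - 1; py <- cand[, 1] - 1   # 0-based (x, y)
  # subpixel refinement: 2-D quadratic fit of the response surface
  gxr <- (R[cbind(cand[, 1], cand[, 2] + 1)] - R[cbind(cand[, 1], cand[, 2] - 1)]) / 2
  gyr <- (R[cbind(cand[, 1] + 1, cand[, 2])] - R[cbind(cand[, 1] - 1, cand[, 2])]) / 2
  hxx <- R[cbind(cand[, 1], cand[, 2] + 1)] + R[cbind(cand[, 1], cand[, 2] - 1)] -
    2 * R[cand]
  hyy <- R[cbind(cand[, 1] + 1, cand[, 2])] + R[cbind(cand[, 1] - 1, cand[, 2])] -
    2 * R[cand]
  hxy <- (R[cbind(cand[, 1] + 1, cand[, 2] + 1)] + R[cbind(cand[, 1] - 1, cand[, 2] - 1)] -
            R[cbind(cand[, 1] + 1, cand[, 2] - 1)] - R[cbind(cand[, 1] - 1, cand[, 2] + 1)]) / 4
  det <- hxx * hyy - hxy^2
  ok <- is.finite(det) & abs(det) > 1e-20
  ox <- ifelse(ok, -(hyy * gxr - hxy * gyr) / det, 0)
  oy <- ifelse(ok, -(hxx * gyr - hxy * gxr) / det, 0)
  ox <- pmin(pmax(ox, -0.5), 0.5)
  oy <- pmin(pmax(oy, -0.5), 0.5)
  px <- px + ox; py <- py + oy
  ori <- dominantOrientations(gr, px, py)
  desc <- keypointDescriptors(g, px, py, ori)
  new("KeypointSet", positions = cbind(px, py, deparse.level = 0),
      descriptors = desc, scores = resp, orientations = ori)
}

# dominant gradient orientation per keypoint (36-bin weighted histogram
# over a Gaussian-weighted 15x15 window)
dominantOrientations <- function(gr, px, py) {
  M <- length(px)
  off <- expand.grid(dx = -7:7, dy = -7:7)
  S <- nrow(off)
  w0 <- exp(-(off$dx^2 + off$dy^2) / (2 * 4.5^2))
  sx <- outer(px, off$dx, "+")          # M x S
  sy <- outer(py, off$dy, "+")
  gx <- matrix(bilinearSample(gr$gx, as.vector(sx), as.vector(sy), fill = 0)[, 1], M, S)
  gy <- matrix(bilinearSample(gr$gy, as.vector(sx), as.vector(sy), fill = 0)[, 1], M, S)
  mag <- sqrt(gx^2 + gy^2) * rep(w0, each = M)
  bin <- (floor((atan2(gy, gx) + pi) / (2 * pi) * 36) %% 36L)
  hist <- matrix(0, M, 36L)
  for (b in 0:35) hist[, b + 1] <- rowSums(mag * (bin == b))
  best <- max.col(hist, ties.method = "first")
  (best - 0.5) / 36 * 2 * pi - pi
}

# 4x4 spatial cells x 8 orientation bins over a rotated 16x16 gradient
# patch; L2-normalized, clipped at 0.2, renormalized
keypointDescriptors <- function(gray, px, py, ori) {
  M <- length(px)
  G <- DESC_GRID
  half <- (G - 1) / 2
  off <- expand.grid(ix = seq_len(G) - 1 - half, iy = seq_len(G) - 1 - half)
  cs <- cos(ori); sn <- sin(ori)
  dx <- off$ix * DESC_SPACING; dy <- off$iy * DESC_SPACING
  sx <- outer(cs, dx) - outer(sn, dy) + px   # M x G^2, ix varies fastest
  sy <- outer(sn, dx) + outer(cs, dy) + py
  vals <- bilinearSample(gray, as.vector(sx), as.vector(sy), fill = 0)[, 1]
  patch <- aperm(array(vals, c(M, G, G)), c(1, 3, 2))  # (M, iy, ix)
  inner <- 2:(G - 1)
  gx <- (patch[, inner, inner + 1, drop = FALSE] -
         patch[, inner, inner - 1, drop = FALSE]) / 2
  gy <- (patch[, inner + 1, inner, drop = FALSE] -
         patch[, inner - 1, inner, drop = FALSE]) / 2
  S <- G - 2L  # 16
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  bin <- (floor((ang + pi) / (2 * pi) * 8) %% 8L)
  cellRow <- (matrix(rep(seq_len(S) - 1L, times = S), S, S) %/% (S %/% 4L))
  cellCol <- (matrix(rep(seq_len(S) - 1L, each = S), S, S) %/% (S %/% 4L))
  cellIdx <- cellRow * 4L + cellCol            # 0..15, per (row, col)
  gw <- exp(-((row(matrix(0, S, S)) - (S + 1) / 2)^2 +
              (col(matrix(0, S, S)) - (S + 1) / 2)^2) / (2 * 6^2))
  desc <- matrix(0, M, 128L)
  for (r in seq_len(S)) for (c in seq_len(S)) {
    d <- cellIdx[r, c] * 8L + bin[, r, c] + 1L
    idx <- cbind(seq_len(M), d)
    desc[idx] <- desc[idx] + mag[, r, c] * gw[r, c]
  }
  nrm <- sqrt(rowSums(desc^2)); nrm[nrm == 0] <- 1
  desc <- desc / nrm
  desc <- pmin(desc, 0.2)
  nrm <- sqrt(rowSums(desc^2)); nrm[nrm == 0] <- 1
  desc / nrm
}

#' Match keypoints by descriptor distance
#'
#' Nearest-neighbour candidates filtered by the Lowe ratio test (a match
#' whose nearest/second-nearest distance ratio exceeds `ratio` is dropped)
#' and, optionally, a mutual-nearest-neighbour check. The result is
#' one-to-one on both sides.
#'
#' @param a,b [KeypointSet-class] objects.
#' @param ratio Lowe ratio threshold in (0, 1].
#' @param mutual require a and b to be each other's nearest neighbours.
#' @return a [MatchSet-class] (empty if either set is empty).
#' @export
matchKeypoints <- function(a, b, ratio = 0.75, mutual = TRUE) {
  emptyMatch <- new("MatchSet", pairs = matrix(integer(0), 0, 2),
                    distances = numeric(0), inlierFlags = logical(0))
  if (nKeypoints(a) == 0L || nKeypoints(b) == 0L) return(emptyMatch)
  D2 <- outer(rowSums(a@descriptors^2), rowSums(b@descriptors^2), "+") -
    2 * a@descriptors %*% t(b@descriptors)
  D2[D2 < 0] <- 0
  nn <- max.col(-D2, ties.method = "first")
  d1 <- sqrt(D2[cbind(seq_len(nrow(D2)), nn)])
  d2 <- vapply(seq_len(nrow(D2)), function(i) {
    row <- D2[i, ]; row[nn[i]] <- Inf
    sqrt(min(row))
  }, 1)
  pass <- d1 <= ratio * d2
  if (mutual) {
    nnB <- max.col(-t(D2), ties.method = "first")
    pass <- pass & (nnB[nn] == seq_along(nn))
  }
  ia <- which(pass); ib <- nn[pass]
  if (any(duplicated(ib))) {   # greedy one-to-one when mutual is off
    ord <- order(d1[ia])
    seen <- logical(nKeypoints(b)); keep <- logical(length(ia))
    for (k in ord) if (!seen[ib[k]]) { seen[ib[k]] <- TRUE; keep[k] <- TRUE }
    ia <- ia[keep]; ib <- ib[keep]
  }
  new("MatchSet", pairs = cbind(ia, ib, deparse.level = 0),
      distances = d1[ia], inlierFlags = rep(TRUE, length(ia)))
}

# closed-form least-squares similarity p -> q via the complex formulation
# w = a z + b (a = s e^{i theta}); reflections cannot be represented
fitSimilarityLS <- function(P, Q, levelMpp = 0.5) {
  z <- complex(real = P[, 1], imaginary = P[, 2])
  w <- complex(real = Q[, 1], imaginary = Q[, 2])
  zc <- mean(z); wc <- mean(w)
  denom <- sum(Mod(z - zc)^2)
  if (denom < 1e-9) stop("degenerate correspondences: coincident points")
  a <- sum((w - wc) * Conj(z - zc)) / denom
  if (Mod(a) < 1e-12) stop("degenerate correspondences: zero scale")
  b <- wc - a * zc
  similarityTransform(theta = Arg(a), scale = Mod(a),
                      tx = Re(b), ty = Im(b), levelMpp = levelMpp)
}

#' Robustly estimate a similarity transform from matches
#'
#' Seeded random-sample consensus over two-point minimal similarity fits,
#' followed by a closed-form least-squares refit on the consensus inliers.
#' Rotation + isotropic scale + translation only: the fitted linear part
#' always has determinant scale^2 > 0.
#'
#' @param matches a [MatchSet-class] between `a` and `b`.
#' @param a,b the [KeypointSet-class] objects the matches index into; the
#'   returned transform maps `a` coordinates into `b` coordinates.
#' @param inlierTolPx inlier residual tolerance (px).
#' @param seed integer seed for the consensus sampling.
#' @param nSamples consensus iterations.
#' @param levelMpp microns-per-pixel tag of the estimation level.
#' @return a [SimilarityTransform2D-class]; attributes `inlierFlags` (per
#'   match) and `nInliers` carry the consensus diagnostics.
#' @export
estimateSimilarity <- function(matches, a, b, inlierTolPx = 3, seed = 1L,
                               nSamples = 300L, levelMpp = 0.5) {
  n <- nrow(matches@pairs)
  if (n < 3L) stop("insufficient matches: need >= 3 candidate pairs, got ", n)
  P <- a@positions[matches@pairs[, 1], , drop = FALSE]
  Q <- b@positions[matches@pairs[, 2], , drop = FALSE]
  spread <- max(stats::sd(P[, 1]), stats::sd(P[, 2]))
  if (!is.finite(spread) || spread < 1e-6)
    stop("degenerate correspondences: coincident points")
  z <- complex(real = P[, 1], imaginary = P[, 2])
  w <- complex(real = Q[, 1], imaginary = Q[, 2])
  best <- NULL; bestCount <- -1L; bestRms <- Inf
  withSeed(seed, {
    for (it in seq_len(nSamples)) {
      ij <- sample.int(n, 2L)
      dz <- z[ij[2]] - z[ij[1]]
      if (Mod(dz) < 1e-9) next
      av <- (w[ij[2]] - w[ij[1]]) / dz
      if (Mod(av) < 1e-12) next
      bv <- w[ij[1]] - av * z[ij[1]]
      res <- Mod(av * z + bv - w)
      inl <- res <= inlierTolPx
      cnt <- sum(inl)
      if (cnt > bestCount ||
          (cnt == bestCount && mean(res[inl]^2) < bestRms)) {
        bestCount <- cnt
        bestRms <- if (cnt > 0) mean(res[inl]^2) else Inf
        best <- inl
      }
    }
  })
  if (is.null(best) || bestCount < 2L)
    stop("degenerate correspondences: consensus failed")
  fit <- fitSimilarityLS(P[best, , drop = FALSE], Q[best, , drop = FALSE],
                         levelMpp = levelMpp)
  res <- Mod(complex(real = P[, 1], imaginary = P[, 2]) *
               complex(real = fit@scale * cos(fit@theta),
                       imaginary = fit@scale * sin(fit@theta)) +
               complex(real = fit@tx, imaginary = fit@ty) - w)
  flags <- res <= inlierTolPx
  if (sum(flags) >= 2L)
    fit <- fitSimilarityLS(P[flags, , drop = FALSE], Q[flags, , drop = FALSE],
                           levelMpp = levelMpp)
  # one tightened refit: drop matches whose residual exceeds half the
  # tolerance so a few sloppy correspondences cannot bias the estimate
  res <- Mod(complex(real = P[, 1], imaginary = P[, 2]) *
               complex(real = fit@scale * cos(fit@theta),
                       imaginary = fit@scale * sin(fit@theta)) +
               complex(real = fit@tx, imaginary = fit@ty) - w)
  tight <- res <= max(inlierTolPx / 2, 1)
  if (sum(tight) >= 10L) {
    fit <- fitSimilarityLS(P[tight, , drop = FALSE], Q[tight, , drop = FALSE],
                           levelMpp = levelMpp)
    flags <- tight
  }
  attr(fit, "inlierFlags") <- flags
  attr(fit, "nInliers") <- sum(flags)
  attr(fit, "nMatches") <- n
  fit
}

#' Serial rigid registration of a section stack
#'
#' The first section is the reference. Each subsequent section is
#' registered against the *already registered rendering* of its
#' predecessor, using only features matched between the two neighbours, so
#' the returned transform maps section-k coordinates directly into the
#' reference frame.
#'
#' @param stack list of [SectionImage-class] (>= 2 sections).
#' @param masks optional list of [TissueMask-class] restricting detection.
#' @param maxKeypoints,ratio,inlierTolPx,seed forwarded to the detector,
#'   matcher, and consensus fit (per-pair seeds are derived from `seed`).
#' @param fallthrough if TRUE, a failing link keeps its predecessor's
#'   transform instead of erroring.
#' @return list of [SimilarityTransform2D-class], the first being the
#'   identity; attribute `pairStats` is a data.frame of per-link match and
#'   inlier counts.
#' @export
registerStackSerial <- function(stack, masks = NULL, maxKeypoints = 500L,
                                ratio = 0.75, inlierTolPx = 3, seed = 1L,
                                fallthrough = FALSE) {
  Z <- length(stack)
  if (Z < 2L) stop("need at least 2 sections")
  mppv <- stack[[1]]@mpp
  transforms <- vector("list", Z)
  transforms[[1]] <- identityTransform(levelMpp = mppv)
  rendered <- stack[[1]]
  renderedMask <- if (!is.null(masks)) masks[[1]] else NULL
  stats <- data.frame(pair = integer(0), n_matches = integer(0),
                      n_inliers = integer(0))
  for (k in 2:Z) {
    ok <- TRUE
    fit <- tryCatch({
      kpPrev <- detectKeypoints(rendered, maxKeypoints, renderedMask)
      kpK <- detectKeypoints(stack[[k]], maxKeypoints,
                             if (!is.null(masks)) masks[[k]] else NULL)
      m <- matchKeypoints(kpK, kpPrev, ratio = ratio)
      estimateSimilarity(m, kpK, kpPrev, inlierTolPx = inlierTolPx,
                         seed = seed + k, levelMpp = mppv)
    }, error = function(e) {
      if (!fallthrough)
        stop("rigid registration failed for pair ", k - 1, "->", k, ": ",
             conditionMessage(e), call. = FALSE)
      ok <<- FALSE
      NULL
    })
    if (ok) {
      transforms[[k]] <- similarityTransform(fit@theta, fit@scale, fit@tx,
                                             fit@ty, levelMpp = mppv)
      stats <- rbind(stats, data.frame(pair = k - 1L,
                                       n_matches = attr(fit, "nMatches"),
                                       n_inliers = attr(fit, "nInliers")))
    } else {
      transforms[[k]] <- transforms[[k - 1]]
      stats <- rbind(stats, data.frame(pair = k - 1L, n_matches = 0L,
                                       n_inliers = 0L))
    }
    rendered <- warpSimilarity(stack[[k]], transforms[[k]])
    if (!is.null(masks))
      renderedMask <- warpMaskSimilarity(masks[[k]], transforms[[k]])
  }
  attr(transforms, "pairStats") <- stats
  transforms
}
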
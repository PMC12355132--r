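# Synthetic serial-section phantom generator.
#
# Emulates a serially sectioned H&E-stained needle-core ribbon: pink stroma
# with dark purple nucleus-like speckle on a white background, elliptical
# gland lumens, per-section similarity misalignment, smooth low-frequency
# non-rigid warps, and landmark points with known cross-section
# correspondence. Every downstream stage of the package is testable against
# the stored ground truth without any external data.

#' Phantom stack specification
#'
#' Parameters of the synthetic serial-section generator. Defaults mirror a
#' routinely sectioned core: 8 ribbons per core (real cores yield 6-16),
#' similarity misalignment of up to 10 degrees rotation, 3% scale and 20 px
#' translation, and a smooth sectioning-distortion warp of ~6 px amplitude
#' on a 64 px control grid.
#'
#' @param nSections number of serial sections (>= 2).
#' @param canvasSize canvas side in pixels.
#' @param nGlands number of elliptical gland lumens.
#' @param maxRotationDeg maximum absolute per-section rotation (degrees).
#' @param scaleRange length-2 interval of per-section isotropic scale; must
#'   contain 1.
#' @param maxTranslationPx maximum absolute per-section translation (px).
#' @param warpAmplitude amplitude of the non-rigid warp (px); 0 disables.
#' @param warpSmoothness control-grid spacing of the warp (px).
#' @param noiseSd additive Gaussian intensity noise (0-255 scale).
#' @param mpp microns per pixel of the phantom sections.
#' @param seed integer seed; equal seeds give bit-identical stacks.
#' @return a validated list of class `PhantomSpec`.
#' @export
phantomSpec <- function(nSections = 8L, canvasSize = 384L, nGlands = 6L,
                        maxRotationDeg = 10, scaleRange = c(0.97, 1.03),
                        maxTranslationPx = 20, warpAmplitude = 6,
                        warpSmoothness = 64, noiseSd = 3, mpp = 0.5,
                        seed = 1L) {
  spec <- list(nSections = as.integer(nSections),
               canvasSize = as.integer(canvasSize), nGlands = as.integer(nGlands),
               maxRotationDeg = maxRotationDeg, scaleRange = scaleRange,
               maxTranslationPx = maxTranslationPx,
               warpAmplitude = warpAmplitude, warpSmoothness = warpSmoothness,
               noiseSd = noiseSd, mpp = mpp, seed = as.integer(seed))
  if (spec$nSections < 2L) stop("nSections must be >= 2")
  if (spec$canvasSize < 32L) stop("canvasSize too small")
  if (spec$nGlands < 0L) stop("nGlands must be >= 0")
  if (length(scaleRange) != 2L || scaleRange[1] > 1 || scaleRange[2] < 1)
    stop("scaleRange must be an interval containing 1")
  if (any(c(spec$maxRotationDeg, spec$maxTranslationPx, spec$warpAmplitude,
            spec$noiseSd) < 0))
    stop("amplitudes must be >= 0")
  if (spec$warpSmoothness <= 0 || spec$mpp <= 0)
    stop("warpSmoothness and mpp must be positive")
  class(spec) <- "PhantomSpec"
  spec
}

# Filled-ellipse mask on an L x L canvas (0-based center coords, radians).
ellipseMask <- function(L, center, a, b, phi = 0) {
  x <- matrix(seq_len(L) - 1, L, L, byrow = TRUE) - center[1]
  y <- matrix(seq_len(L) - 1, L, L) - center[2]
  xr <- x * cos(phi) + y * sin(phi)
  yr <- -x * sin(phi) + y * cos(phi)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# Curved ribbon band: circular-arc centerline of radius R spanning
# +/- alphaH around "up", half-width b tapering elliptically to rounded
# ends, rotated by phi about the canvas center. Serial-section ribbons
# bow as they come off the block, so the phantom tissue is an arc, not a
# straight strip.
ribbonGeomPoint <- function(geom, s, radialFrac = 0) {
  # point on/off the centerline at arc parameter s in [0, 1]
  ang <- (2 * s - 1) * geom$alphaH
  halfw <- geom$b * sqrt(pmax(0, 1 - (2 * s - 1)^2))
  r <- geom$R + radialFrac * halfw
  p <- cbind(geom$arcCenter[1] + r * sin(ang),
             geom$arcCenter[2] - r * cos(ang))
  rotatePoints(p, geom$phi, geom$center)
}

rotatePoints <- function(p, phi, about) {
  dx <- p[, 1] - about[1]; dy <- p[, 2] - about[2]
  cbind(about[1] + dx * cos(phi) - dy * sin(phi),
        about[2] + dx * sin(phi) + dy * cos(phi))
}

ribbonBandMask <- function(L, geom) {
  x <- matrix(seq_len(L) - 1, L, L, byrow = TRUE) - geom$center[1]
  y <- matrix(seq_len(L) - 1, L, L) - geom$center[2]
  xr <- x * cos(-geom$phi) - y * sin(-geom$phi) + geom$center[1] - geom$arcCenter[1]
  yr <- x * sin(-geom$phi) + y * cos(-geom$phi) + geom$center[2] - geom$arcCenter[2]
  r <- sqrt(xr^2 + yr^2)
  ang <- atan2(xr, -yr)
  s <- (ang / geom$alphaH + 1) / 2
  halfw <- geom$b * sqrt(pmax(0, 1 - (2 * pmin(pmax(s, 0), 1) - 1)^2))
  abs(ang) <= geom$alphaH & abs(r - geom$R) <= halfw
}

# Smooth random scalar field from a coarse control grid (B-spline upsampled).
smoothRandomField <- function(L, spacing, sd, clamp = Inf) {
  B <- bsplineBasis(L, spacing)
  C <- matrix(stats::rnorm(ncol(B)^2, sd = sd), ncol(B), ncol(B))
  C <- pmin(pmax(C, -clamp), clamp)
  B %*% C %*% t(B)
}

# Scene for one depth level: tissue/gland geometry plus landmark points.
phantomScene <- function(spec, geom, depthFactor) {
  L <- spec$canvasSize
  tissue <- geom$tissue
  glandMask <- matrix(FALSE, L, L)
  for (g in seq_len(nrow(geom$glands))) {
    gl <- geom$glands[g, ]
    glandMask <- glandMask |
      ellipseMask(L, c(gl["cx"], gl["cy"]),
                  gl["ga"] * depthFactor, gl["gb"] * depthFactor, gl["gphi"])
  }
  fg <- tissue & !glandMask
  img <- array(255, c(L, L, 3L))
  stroma <- c(214, 150, 196)  # eosin-pink, hue in the magenta band
  for (c in 1:3) {
    plane <- matrix(255, L, L)
    plane[fg] <- stroma[c] * geom$shade[fg]
    img[, , c] <- plane
  }
  # nucleus speckle: dark purple dots of varying size and darkness, fixed
  # across depth so adjacent sections share matchable structure
  nuc <- c(92, 58, 138)
  keep <- fg[cbind(geom$nuclei[, 2] + 1, geom$nuclei[, 1] + 1)]
  dots <- geom$nuclei[keep, , drop = FALSE]
  shade <- geom$nucShade[keep]
  big <- geom$nucBig[keep]
  stampDots <- function(sel, offsets) {
    for (o in offsets) {
      yy <- dots[sel, 2] + o[2]; xx <- dots[sel, 1] + o[1]
      ok <- yy >= 0 & yy < L & xx >= 0 & xx < L
      idx <- cbind(yy[ok] + 1, xx[ok] + 1)
      for (c in 1:3) {
        plane <- img[, , c]
        plane[idx] <- nuc[c] * shade[sel][ok]
        img[, , c] <<- plane
      }
    }
  }
  o3 <- lapply(seq_len(9), function(k) c((k - 1) %% 3 - 1, (k - 1) %/% 3 - 1))
  o5 <- Filter(function(o) sum(abs(o)) <= 2,
               lapply(seq_len(25), function(k) c((k - 1) %% 5 - 2, (k - 1) %/% 5 - 2)))
  stampDots(!big, o3)
  stampDots(big, o5)
  list(img = img, truth = fg)
}

# Fixed scene geometry drawn once per phantom (reference frame).
phantomGeometry <- function(spec) {
  L <- spec$canvasSize
  center <- c(L / 2, L / 2)
  # curved ribbon band: needle-core ribbons are millimetres wide,
  # centimetres long, and bow as they come off the microtome
  R <- 0.57 * L
  alphaH <- 0.70            # half the angular span (radians)
  b <- 0.06 * L             # half-width of the band
  phi <- stats::runif(1, 0, 2 * pi)
  # place the band's bounding box at the canvas center before rotation
  arcCenter <- c(L / 2, L / 2 + R * (1 + cos(alphaH)) / 2)
  geom <- list(center = center, arcCenter = arcCenter, R = R,
               alphaH = alphaH, b = b, phi = phi)
  geom$tissue <- ribbonBandMask(L, geom)
  glands <- matrix(numeric(0), 0, 5,
                   dimnames = list(NULL, c("cx", "cy", "ga", "gb", "gphi")))
  if (spec$nGlands > 0) {
    svals <- seq(0.12, 0.88, length.out = spec$nGlands)
    gc <- ribbonGeomPoint(geom, svals,
                          radialFrac = stats::runif(spec$nGlands, -0.3, 0.3))
    for (k in seq_len(spec$nGlands)) {
      glands <- rbind(glands, c(gc[k, 1], gc[k, 2],
                                stats::runif(1, 0.012, 0.020) * L,
                                stats::runif(1, 0.008, 0.014) * L,
                                stats::runif(1, 0, pi)))
    }
  }
  geom$glands <- glands
  nNuc <- round(0.0025 * L^2)
  tisIdx <- which(geom$tissue, arr.ind = TRUE)
  pick <- sample.int(nrow(tisIdx), min(nNuc, nrow(tisIdx)))
  nuclei <- cbind(tisIdx[pick, 2] - 1, tisIdx[pick, 1] - 1)
  geom$nuclei <- nuclei
  geom$nucShade <- stats::runif(nrow(nuclei), 0.6, 1.4)
  geom$nucBig <- stats::runif(nrow(nuclei)) < 0.4
  # stain texture: low-frequency shading plus mid-frequency mottle, so
  # local neighbourhoods are distinctive for keypoint matching
  geom$shade <- 1 + smoothRandomField(L, L / 5, sd = 0.05, clamp = 0.12) +
    smoothRandomField(L, 16, sd = 0.06, clamp = 0.18)
  # landmarks: points on both band edges plus gland centers
  sB <- seq(0.08, 0.92, length.out = 6L)
  lm <- rbind(ribbonGeomPoint(geom, sB, radialFrac = 0.9),
              ribbonGeomPoint(geom, sB, radialFrac = -0.9),
              if (nrow(glands)) glands[, c("cx", "cy"), drop = FALSE])
  dimnames(lm) <- NULL
  geom$landmarks <- lm
  geom
}

# analytic tissue area of the band minus the gland lumens (px^2)
phantomAnalyticArea <- function(geom, depthFactor = 1) {
  band <- pi * geom$b * geom$R * geom$alphaH
  glands <- if (nrow(geom$glands))
    sum(pi * geom$glands[, "ga"] * geom$glands[, "gb"]) * depthFactor^2 else 0
  band - glands
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' Section t is the base tissue scene, slightly morphed with depth (gland
#' lumens dilate/contract through the stack), pushed through a ground-truth
#' similarity misalignment and a smooth non-rigid warp, then corrupted with
#' additive noise. The stored `trueTransforms` map section-t coordinates
#' into reference (section 1) coordinates -- exactly what the rigid stage
#' must recover. Landmarks are the corrupted images' coordinates of fixed
#' anatomical points (gland centers and boundary points).
#'
#' @param spec a [phantomSpec()].
#' @return a [PhantomStack-class].
#' @export
generatePhantomCore <- function(spec) {
  if (!inherits(spec, "PhantomSpec")) spec <- do.call(phantomSpec, spec)
  withSeed(spec$seed, {
    geom <- phantomGeometry(spec)
    Z <- spec$nSections
    L <- spec$canvasSize
    c0 <- geom$center
    sections <- vector("list", Z); transforms <- vector("list", Z)
    warps <- vector("list", Z); lms <- vector("list", Z); truths <- vector("list", Z)
    zeroField <- displacementField(matrix(0, L, L), matrix(0, L, L),
                                   gridSpacingPx = spec$warpSmoothness)
    for (t in seq_len(Z)) {
      depthFactor <- 1 + 0.2 * (t - 1 - (Z - 1) / 2) / max(1, (Z - 1) / 2)
      scene <- phantomScene(spec, geom, depthFactor)
      if (t == 1L) {
        tt <- identityTransform(levelMpp = spec$mpp)
        wf <- zeroField
      } else {
        theta <- stats::runif(1, -spec$maxRotationDeg, spec$maxRotationDeg) * pi / 180
        s <- stats::runif(1, spec$scaleRange[1], spec$scaleRange[2])
        tr <- stats::runif(2, -spec$maxTranslationPx, spec$maxTranslationPx)
        # rotate/scale about the canvas center, then translate
        A <- s * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
        toff <- c0 - A %*% c0 + tr
        tt <- similarityTransform(theta = theta, scale = s,
                                  tx = toff[1], ty = toff[2], levelMpp = spec$mpp)
        wf <- if (spec$warpAmplitude > 0) {
          # warpAmplitude is the peak |displacement| of the dense field
          u0 <- smoothRandomField(L, spec$warpSmoothness, sd = 1)
          v0 <- smoothRandomField(L, spec$warpSmoothness, sd = 1)
          sc <- spec$warpAmplitude / max(sqrt(u0^2 + v0^2))
          displacementField(u0 * sc, v0 * sc,
                            gridSpacingPx = spec$warpSmoothness)
        } else zeroField
      }
      base <- SectionImage(scene$img, mpp = spec$mpp)
      rigidImg <- if (t == 1L) base else warpSimilarity(base, invertTransform(tt))
      img <- if (spec$warpAmplitude > 0 && t > 1L) warpDense(rigidImg, wf) else rigidImg
      if (spec$noiseSd > 0) {
        noisy <- img@data + array(stats::rnorm(length(img@data), sd = spec$noiseSd),
                                  dim(img@data))
        img <- SectionImage(pmin(pmax(noisy, 0), 255), mpp = spec$mpp)
      }
      lmRigid <- if (t == 1L) geom$landmarks else
        transformPoints(geom$landmarks, invertTransform(tt))
      lms[[t]] <- if (spec$warpAmplitude > 0 && t > 1L)
        invertFieldPoints(lmRigid, wf) else lmRigid
      truthRef <- TissueMask(scene$truth * 1, mpp = spec$mpp)
      truthT <- if (t == 1L) truthRef else
        warpMaskSimilarity(truthRef, invertTransform(tt))
      if (spec$warpAmplitude > 0 && t > 1L) truthT <- warpMaskDense(truthT, wf)
      sections[[t]] <- img
      transforms[[t]] <- tt
      warps[[t]] <- wf
      truths[[t]] <- truthT@mask
    }
    new("PhantomStack", sections = sections, trueTransforms = transforms,
        trueWarps = warps, landmarks = lms, tissueTruth = truths)
  })
}

# Where does a source point land after a backward-mapping warp?
# Solves q + d(q) = p by fixed-point iteration (fields are smooth and
# small, so convergence is fast).
invertFieldPoints <- function(points, field, iters = 20L) {
  q <- points
  for (i in seq_len(iters)) {
    du <- bilinearSample(field@u, q[, 1], q[, 2], fill = 0)[, 1]
    dv <- bilinearSample(field@v, q[, 1], q[, 2], fill = 0)[, 1]
    q <- cbind(points[, 1] - du, points[, 2] - dv)
  }
  q
}

#' Downsample a section into a resolution pyramid
#'
#' Level k is the original block-averaged by `factors[k]` (dimensions
#' floored), with microns-per-pixel multiplied by the factor -- the same
#' relationship that lets a 40x scan at 0.25 um/px be worked at 20x
#' (0.5 um/px).
#'
#' @param img a [SectionImage-class].
#' @param factors integer downsampling factors, ascending, all >= 1.
#' @return list of [SectionImage-class], one per factor.
#' @export
downsamplePyramid <- function(img, factors) {
  factors <- as.integer(factors)
  if (any(factors < 1L)) stop("factors must be >= 1")
  if (is.unsorted(factors)) stop("factors must be ascending")
  d <- dim(img@data)
  lapply(factors, function(f) {
    H <- d[1] %/% f; W <- d[2] %/% f
    if (H < 1L || W < 1L) stop("factor ", f, " larger than image")
    if (f == 1L) return(img)
    out <- array(0, c(H, W, 3L))
    cropped <- img@data[seq_len(H * f), seq_len(W * f), , drop = FALSE]
    for (c in 1:3) {
      m <- cropped[, , c]
      dim(m) <- c(f, H, f, W)
      out[, , c] <- apply(m, c(2, 4), mean)
    }
    SectionImage(out, mpp = img@mpp * f, offset = img@offset / f)
  })
}
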
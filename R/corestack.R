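# 2.5D core assembly, patch extraction, and the registration-error
# statistic.

#' Assemble a co-registered 2.5D core
#'
#' @param alignedSections list of co-registered [SectionImage-class] of
#'   identical shape (Z >= 2).
#' @param masks list of per-section [TissueMask-class].
#' @param mpp microns per pixel of the stack.
#' @param provenance optional list recording the transform chain and
#'   pipeline settings.
#' @return a [Core25D-class].
#' @export
assembleCore <- function(alignedSections, masks, mpp, provenance = list()) {
  Z <- length(alignedSections)
  if (Z < 2L) stop("a 2.5D core needs at least 2 sections")
  if (length(masks) != Z) stop("need one mask per section")
  ref <- dim(alignedSections[[1]]@data)[1:2]
  for (k in seq_len(Z)) {
    dk <- dim(alignedSections[[k]]@data)[1:2]
    if (!identical(dk, ref))
      stop("section ", k, " has shape ", dk[1], "x", dk[2],
           " but the reference is ", ref[1], "x", ref[2])
    if (!identical(dim(maskData(masks[[k]])), ref))
      stop("mask ", k, " does not match the section shape")
  }
  new("Core25D", volume = alignedSections, masks = masks, mpp = mpp,
      provenance = provenance)
}

#' Tissue fraction of one 2.5D window
#'
#' The fraction is the mean over the Z per-section masks of the in-window
#' tissue-pixel fraction (symmetric in depth: no privileged reference
#' section).
#'
#' @param core a [Core25D-class].
#' @param origin 0-based (x, y) of the window's top-left corner.
#' @param patchPx window side in pixels.
#' @return a real in [0, 1].
#' @export
patchTissueFraction <- function(core, origin, patchPx = 256L) {
  d <- dim(core@volume[[1]]@data)
  x0 <- origin[1]; y0 <- origin[2]
  if (x0 < 0 || y0 < 0 || x0 + patchPx > d[2] || y0 + patchPx > d[1])
    stop("window at (", x0, ", ", y0, ") falls outside the core")
  fr <- vapply(core@masks, function(m)
    mean(maskData(m)[(y0 + 1):(y0 + patchPx), (x0 + 1):(x0 + patchPx)]), 1)
  mean(fr)
}

#' Extract non-overlapping 2.5D patches
#'
#' Tiles the core on a `patchPx` grid anchored at the top-left of the
#' tissue union bounding box (stride = patch size, so tiles never
#' overlap). Partial edge tiles are discarded, and a tile is kept only if
#' its stack-mean tissue fraction is *strictly* greater than
#' `minFraction` -- a window at exactly the threshold is excluded.
#'
#' @param core a [Core25D-class].
#' @param patchPx patch side in pixels.
#' @param minFraction strict lower bound on the tissue fraction.
#' @return list of [Patch25D-class] (possibly empty).
#' @export
extractPatches <- function(core, patchPx = 256L, minFraction = 0.6) {
  d <- dim(core@volume[[1]]@data)
  reg <- tryCatch(buildRegistrationMask(core@masks), error = function(e) NULL)
  if (is.null(reg)) return(list())
  bb <- reg$bbox
  if (bb[3] - bb[1] < patchPx || bb[4] - bb[2] < patchPx) return(list())
  xs <- seq(bb[1], bb[3] - patchPx, by = patchPx)
  ys <- seq(bb[2], bb[4] - patchPx, by = patchPx)
  Z <- length(core@volume)
  out <- list()
  for (y0 in ys) for (x0 in xs) {
    fr <- patchTissueFraction(core, c(x0, y0), patchPx)
    if (fr > minFraction) {
      dat <- array(0, c(Z, patchPx, patchPx, 3L))
      for (t in seq_len(Z))
        dat[t, , , ] <- core@volume[[t]]@data[(y0 + 1):(y0 + patchPx),
                                              (x0 + 1):(x0 + patchPx), ]
      out[[length(out) + 1L]] <- new("Patch25D", origin = c(x0, y0),
                                     data = dat, tissueFraction = fr)
    }
  }
  out
}

#' Registration error between one pair of matched keypoint sets
#'
#' The per-pair statistic is the median Euclidean distance, in microns,
#' between matched keypoints of two subsequent sections in the stack.
#'
#' @param pointsA,pointsB equal-length M x 2 matrices of matched 0-based
#'   pixel coordinates.
#' @param mpp microns per pixel.
#' @return list(medianUm, nMatches).
#' @export
pairRegistrationError <- function(pointsA, pointsB, mpp) {
  pointsA <- rbind(pointsA); pointsB <- rbind(pointsB)
  if (nrow(pointsA) == 0L) stop("no matched keypoints")
  if (nrow(pointsA) != nrow(pointsB)) stop("point lists differ in length")
  d <- sqrt(rowSums((pointsA - pointsB)^2)) * mpp
  list(medianUm = stats::median(d), nMatches = nrow(pointsA))
}

#' Core-level registration error
#'
#' Weighted mean of the per-pair median distances, weighted by the number
#' of matched features per pair of images.
#'
#' @param reportPairs data.frame with columns median_um and n_matches (one
#'   row per subsequent-section pair).
#' @return the core error in microns.
#' @export
coreRegistrationError <- function(reportPairs) {
  if (nrow(reportPairs) == 0L) stop("no pair entries")
  w <- reportPairs$n_matches
  if (sum(w) == 0) stop("zero total matches")
  sum(reportPairs$median_um * w) / sum(w)
}

#' Registration error of a whole stack
#'
#' For every pair of subsequent sections, detects keypoints on both
#' (final, aligned) images, matches them (mutual nearest neighbour + Lowe
#' ratio), and scores the median matched-keypoint distance in microns; the
#' per-pair medians are aggregated with [coreRegistrationError()]. Both
#' registered and unregistered stacks are scored by the same procedure, so
#' conditions are compared on the same match population.
#'
#' @param sections list of [SectionImage-class].
#' @param masks optional list of [TissueMask-class].
#' @param mpp microns per pixel; defaults to the first section's.
#' @param maxKeypoints,ratio forwarded to detector/matcher.
#' @return a [RegistrationReport-class].
#' @export
stackRegistrationError <- function(sections, masks = NULL, mpp = NULL,
                                   maxKeypoints = 500L, ratio = 0.75) {
  Z <- length(sections)
  if (Z < 2L) stop("need at least 2 sections")
  if (is.null(mpp)) mpp <- sections[[1]]@mpp
  kps <- lapply(seq_len(Z), function(k)
    detectKeypoints(sections[[k]], maxKeypoints,
                    if (!is.null(masks)) masks[[k]] else NULL))
  rows <- data.frame(pair = integer(0), median_um = numeric(0),
                     n_matches = integer(0))
  for (k in 2:Z) {
    m <- matchKeypoints(kps[[k - 1]], kps[[k]], ratio = ratio)
    if (nrow(m@pairs) == 0L) next
    pe <- pairRegistrationError(kps[[k - 1]]@positions[m@pairs[, 1], , drop = FALSE],
                                kps[[k]]@positions[m@pairs[, 2], , drop = FALSE],
                                mpp)
    rows <- rbind(rows, data.frame(pair = k - 1L, median_um = pe$medianUm,
                                   n_matches = pe$nMatches))
  }
  if (nrow(rows) == 0L) stop("no matched keypoints in any pair")
  new("RegistrationReport", perPair = rows,
      coreErrorUm = coreRegistrationError(rows))
}
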
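#' @import methods
NULL

#' SectionImage: one 2-D RGB section with resolution metadata
#'
#' The atomic unit of the registration pipeline: an H x W x 3 intensity
#' array (values in [0, 255]) together with its microns-per-pixel scale and
#' the 0-based (x, y) offset of its top-left corner in the parent image
#' (non-zero after cropping, so coordinates can be mapped back).
#'
#' @slot data numeric H x W x 3 array, intensities in [0, 255].
#' @slot mpp microns per pixel (0.25 at 40x scans, 0.5 at 20x).
#' @slot offset numeric length-2 (x0, y0) offset into the parent image.
#' @export
setClass("SectionImage",
  representation(data = "array", mpp = "numeric", offset = "numeric"),
  prototype(offset = c(0, 0)),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L || d[3] != 3L) return("data must be H x W x 3")
    if (d[1] < 1L || d[2] < 1L) return("zero-size image")
    if (length(object@mpp) != 1L || object@mpp <= 0) return("mpp must be a positive scalar")
    if (length(object@offset) != 2L) return("offset must be length 2")
    TRUE
  })

#' Construct a SectionImage
#' @param data H x W x 3 numeric array in [0, 255] (an H x W matrix is
#'   replicated across channels).
#' @param mpp microns per pixel.
#' @param offset (x0, y0) offset of this crop in its parent image.
#' @return a [SectionImage-class] object.
#' @export
SectionImage <- function(data, mpp = 0.5, offset = c(0, 0)) {
  if (is.matrix(data)) data <- array(rep(data, 3L), c(dim(data), 3L))
  new("SectionImage", data = data, mpp = mpp, offset = as.numeric(offset))
}

#' @describeIn SectionImage-class pixel array accessor
#' @param x a SectionImage
#' @export
sectionData <- function(x) x@data

#' @describeIn SectionImage-class microns-per-pixel accessor
#' @export
mpp <- function(x) x@mpp

setMethod("show", "SectionImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("SectionImage %d x %d px, %.3f um/px, offset (%g, %g)\n",
              d[2], d[1], object@mpp, object@offset[1], object@offset[2]))
})

#' TissueMask: binary foreground mask of one section
#'
#' @slot mask binary (0/1) matrix, same height/width as the source image.
#' @slot mpp microns per pixel at which the mask was computed.
#' @export
setClass("TissueMask",
  representation(mask = "matrix", mpp = "numeric"),
  validity = function(object) {
    if (!all(object@mask %in% c(0, 1))) return("mask values must be 0/1")
    if (object@mpp <= 0) return("mpp must be positive")
    TRUE
  })

#' Construct a TissueMask
#' @param mask binary matrix.
#' @param mpp microns per pixel.
#' @export
TissueMask <- function(mask, mpp = 0.5) {
  storage.mode(mask) <- "double"
  new("TissueMask", mask = mask, mpp = mpp)
}

#' @describeIn TissueMask-class binary matrix accessor
#' @param x a TissueMask
#' @export
maskData <- function(x) x@mask

setMethod("show", "TissueMask", function(object) {
  cat(sprintf("TissueMask %d x %d px, tissue fraction %.3f\n",
              ncol(object@mask), nrow(object@mask), mean(object@mask)))
})

#' SimilarityTransform2D: rotation + isotropic scale + translation
#'
#' Maps a 0-based (x right, y down) point p to s * R(theta) p + (tx, ty)
#' with R(theta) = [[cos, -sin], [sin, cos]]; a 90 degree rotation sends
#' (1, 0) to (0, 1). The linear part has determinant s^2 > 0, so no
#' reflection or shear can be represented -- the property that makes the
#' rigid stage morphology-preserving.
#'
#' @slot theta rotation in radians.
#' @slot scale isotropic scale (> 0).
#' @slot tx,ty translation in pixels.
#' @slot levelMpp microns-per-pixel of the level the transform was
#'   estimated at.
#' @export
setClass("SimilarityTransform2D",
  representation(theta = "numeric", scale = "numeric",
                 tx = "numeric", ty = "numeric", levelMpp = "numeric"),
  prototype(theta = 0, scale = 1, tx = 0, ty = 0, levelMpp = 0.5),
  validity = function(object) {
    if (object@scale <= 0) return("scale must be > 0")
    if (!all(is.finite(c(object@theta, object@scale, object@tx, object@ty))))
      return("non-finite transform parameters")
    TRUE
  })

#' Construct a SimilarityTransform2D
#' @param theta rotation (radians).
#' @param scale isotropic scale, must be positive.
#' @param tx,ty translation (px).
#' @param levelMpp microns-per-pixel the transform applies at.
#' @return a [SimilarityTransform2D-class].
#' @export
similarityTransform <- function(theta = 0, scale = 1, tx = 0, ty = 0,
                                levelMpp = 0.5) {
  new("SimilarityTransform2D", theta = theta, scale = scale,
      tx = tx, ty = ty, levelMpp = levelMpp)
}

#' Identity transform
#' @param levelMpp microns-per-pixel tag.
#' @export
identityTransform <- function(levelMpp = 0.5) similarityTransform(levelMpp = levelMpp)

setMethod("show", "SimilarityTransform2D", function(object) {
  cat(sprintf(
    "SimilarityTransform2D theta %.4f deg, scale %.5f, t (%.2f, %.2f) px @ %.3f um/px\n",
    object@theta * 180 / pi, object@scale, object@tx, object@ty, object@levelMpp))
})

#' DisplacementField: dense backward-mapping 2-D vector field
#'
#' Resampling convention: the warped image value at output pixel (x, y) is
#' the source image sampled at (x + u(x, y), y + v(x, y)).
#'
#' @slot u,v numeric matrices (px), same shape as the target image.
#' @slot gridSpacingPx control-grid spacing of the free-form
#'   parameterization the field came from.
#' @export
setClass("DisplacementField",
  representation(u = "matrix", v = "matrix", gridSpacingPx = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@u), dim(object@v))) return("u/v shape mismatch")
    if (!all(is.finite(object@u)) || !all(is.finite(object@v)))
      return("field must be finite everywhere")
    TRUE
  })

#' Construct a DisplacementField
#' @param u,v displacement components (px), backward mapping.
#' @param gridSpacingPx control-grid spacing (px).
#' @export
displacementField <- function(u, v, gridSpacingPx = 64) {
  new("DisplacementField", u = u, v = v, gridSpacingPx = gridSpacingPx)
}

setMethod("show", "DisplacementField", function(object) {
  mag <- sqrt(object@u^2 + object@v^2)
  cat(sprintf("DisplacementField %d x %d px, |d| max %.2f px, grid %g px\n",
              ncol(object@u), nrow(object@u), max(mag), object@gridSpacingPx))
})

#' KeypointSet: detected interest points with descriptors
#'
#' @slot positions M x 2 matrix of 0-based (x, y) pixel coordinates.
#' @slot descriptors M x d matrix of descriptor vectors.
#' @slot scores per-keypoint detector responses.
#' @slot orientations per-keypoint dominant gradient orientation (radians).
#' @export
setClass("KeypointSet",
  representation(positions = "matrix", descriptors = "matrix",
                 scores = "numeric", orientations = "numeric"),
  validity = function(object) {
    m <- nrow(object@positions)
    if (m > 0 && (!all(is.finite(object@positions)))) return("non-finite positions")
    if (nrow(object@descriptors) != m) return("descriptor count mismatch")
    TRUE
  })

setMethod("show", "KeypointSet", function(object) {
  cat(sprintf("KeypointSet with %d keypoints (descriptor dim %d)\n",
              nrow(object@positions), ncol(object@descriptors)))
})

#' @describeIn KeypointSet-class number of keypoints
#' @param x a KeypointSet
#' @export
nKeypoints <- function(x) nrow(x@positions)

#' MatchSet: one-to-one candidate correspondences between two KeypointSets
#'
#' @slot pairs n x 2 integer matrix (index in A, index in B), one-to-one.
#' @slot distances descriptor distances per pair.
#' @slot inlierFlags logical flags set by the robust similarity fit.
#' @export
setClass("MatchSet",
  representation(pairs = "matrix", distances = "numeric",
                 inlierFlags = "logical"),
  validity = function(object) {
    n <- nrow(object@pairs)
    if (n > 0) {
      if (anyDuplicated(object@pairs[, 1]) || anyDuplicated(object@pairs[, 2]))
        return("match indices must be unique on each side")
    }
    if (length(object@inlierFlags) != n) return("inlierFlags length mismatch")
    TRUE
  })

setMethod("show", "MatchSet", function(object) {
  cat(sprintf("MatchSet with %d pairs (%d inliers)\n",
              nrow(object@pairs), sum(object@inlierFlags)))
})

#' PhantomStack: synthetic serial-section stack with ground truth
#'
#' @slot sections list of [SectionImage-class].
#' @slot trueTransforms list of [SimilarityTransform2D-class]; element t maps
#'   section-t coordinates INTO reference (section 1) coordinates; the first
#'   is the identity.
#' @slot trueWarps list of [DisplacementField-class] (backward, section grid).
#' @slot landmarks list of M x 2 point matrices with cross-section
#'   correspondence (row i of every section is the same anatomical point).
#' @slot tissueTruth list of binary matrices.
#' @export
setClass("PhantomStack",
  representation(sections = "list", trueTransforms = "list",
                 trueWarps = "list", landmarks = "list",
                 tissueTruth = "list"),
  validity = function(object) {
    n <- length(object@sections)
    if (length(object@trueTransforms) != n || length(object@trueWarps) != n ||
        length(object@landmarks) != n || length(object@tissueTruth) != n)
      return("per-section lists must have equal length")
    m <- vapply(object@landmarks, nrow, 1L)
    if (n > 0 && length(unique(m)) != 1L)
      return("landmark sets must have identical cardinality across sections")
    t0 <- object@trueTransforms[[1]]
    if (n > 0 && (abs(t0@theta) > 1e-12 || abs(t0@scale - 1) > 1e-12 ||
                  abs(t0@tx) > 1e-12 || abs(t0@ty) > 1e-12))
      return("trueTransforms[[1]] must be the identity")
    TRUE
  })

setMethod("show", "PhantomStack", function(object) {
  cat(sprintf("PhantomStack with %d sections, %d landmarks/section\n",
              length(object@sections),
              if (length(object@landmarks)) nrow(object@landmarks[[1]]) else 0L))
})

#' @describeIn PhantomStack-class number of sections
#' @param x a PhantomStack
#' @export
nSections <- function(x) length(x@sections)

#' Core25D: co-registered z-stack of one biopsy core
#'
#' @slot volume list of Z co-registered [SectionImage-class] of equal shape.
#' @slot masks list of per-section [TissueMask-class].
#' @slot mpp microns per pixel of the co-registered stack.
#' @slot provenance list carrying the transform chain / pipeline metadata.
#' @export
setClass("Core25D",
  representation(volume = "list", masks = "list", mpp = "numeric",
                 provenance = "list"),
  prototype(provenance = list()),
  validity = function(object) {
    z <- length(object@volume)
    if (z < 2L) return("a 2.5D core needs Z >= 2 sections")
    if (length(object@masks) != z) return("one mask per section required")
    dims <- vapply(object@volume, function(s) dim(s@data)[1:2], numeric(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      return("all sections must share one shape")
    if (object@mpp <= 0) return("mpp must be positive")
    TRUE
  })

setMethod("show", "Core25D", function(object) {
  d <- dim(object@volume[[1]]@data)
  cat(sprintf("Core25D Z=%d, %d x %d px @ %.3f um/px\n",
              length(object@volume), d[2], d[1], object@mpp))
})

#' @describeIn Core25D-class number of sections (depth Z)
#' @param x a Core25D
#' @export
coreDepth <- function(x) length(x@volume)

#' Patch25D: one non-overlapping 2.5D tile of a core
#'
#' @slot origin 0-based (x, y) of the tile's top-left corner in core
#'   coordinates.
#' @slot data Z x P x P x 3 array.
#' @slot tissueFraction mean in-window tissue fraction across the stack;
#'   every emitted patch satisfies tissueFraction > 0.6.
#' @export
setClass("Patch25D",
  representation(origin = "numeric", data = "array",
                 tissueFraction = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 4L) return("data must be Z x P x P x 3")
    if (object@tissueFraction < 0 || object@tissueFraction > 1)
      return("tissueFraction outside [0, 1]")
    TRUE
  })

setMethod("show", "Patch25D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Patch25D %dx%dx%d at (%g, %g), tissue %.3f\n",
              d[1], d[2], d[3], object@origin[1], object@origin[2],
              object@tissueFraction))
})

#' RegistrationReport: per-pair and core-level registration error
#'
#' @slot perPair data.frame with columns pair, median_um, n_matches.
#' @slot coreErrorUm match-count-weighted mean of the per-pair medians.
#' @export
setClass("RegistrationReport",
  representation(perPair = "data.frame", coreErrorUm = "numeric"),
  validity = function(object) {
    need <- c("pair", "median_um", "n_matches")
    if (!all(need %in% names(object@perPair)))
      return("perPair needs columns pair, median_um, n_matches")
    TRUE
  })

setMethod("show", "RegistrationReport", function(object) {
  cat(sprintf("RegistrationReport: %d pairs, core error %.2f um\n",
              nrow(object@perPair), object@coreErrorUm))
})

#' @describeIn RegistrationReport-class weighted core-level error (um)
#' @param x a RegistrationReport
#' @export
coreError <- function(x) x@coreErrorUm
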
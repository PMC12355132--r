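# Similarity-transform algebra and image resampling.

transformMatrix <- function(t) {
  cs <- cos(t@theta); sn <- sin(t@theta)
  t@scale * matrix(c(cs, sn, -sn, cs), 2, 2)  # columns: image of e_x, e_y
}

#' Apply a similarity transform to a point set
#'
#' Computes p' = s R(theta) p + (tx, ty) per point, in the package's
#' x = column / y-down convention.
#'
#' @param points M x 2 matrix of 0-based (x, y) coordinates.
#' @param t a [SimilarityTransform2D-class].
#' @return M x 2 matrix of transformed coordinates.
#' @export
transformPoints <- function(points, t) {
  points <- rbind(points)  # accept a bare length-2 vector
  stopifnotFinite(points, "points")
  A <- transformMatrix(t)
  out <- points %*% t(A)
  out[, 1] <- out[, 1] + t@tx
  out[, 2] <- out[, 2] + t@ty
  out
}

#' Invert a similarity transform
#' @param t a [SimilarityTransform2D-class].
#' @return the inverse transform (same class; scale 1/s, rotation -theta).
#' @export
invertTransform <- function(t) {
  A <- transformMatrix(t)
  Ainv <- solve(A)
  tb <- -Ainv %*% c(t@tx, t@ty)
  similarityTransform(theta = -t@theta, scale = 1 / t@scale,
                      tx = tb[1], ty = tb[2], levelMpp = t@levelMpp)
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `first` and then `second`
#' (angles add, scales multiply: the family is closed under composition).
#'
#' @param second,first [SimilarityTransform2D-class] objects.
#' @export
composeTransforms <- function(second, first) {
  A2 <- transformMatrix(second)
  tb <- A2 %*% c(first@tx, first@ty) + c(second@tx, second@ty)
  similarityTransform(theta = second@theta + first@theta,
                      scale = second@scale * first@scale,
                      tx = tb[1], ty = tb[2], levelMpp = first@levelMpp)
}

#' Propagate a transform across resolution levels
#'
#' The translation scales linearly with the downsampling factor while the
#' rotation angle and scale factor are resolution-independent, so a
#' transform estimated on a downsampled level can be applied at full
#' resolution by multiplying (tx, ty) by the factor.
#'
#' @param t a [SimilarityTransform2D-class].
#' @param factor resolution ratio (> 0); e.g. 8 to go from a 1/8 level to
#'   the original resolution.
#' @export
rescaleTransform <- function(t, factor) {
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0")
  similarityTransform(theta = t@theta, scale = t@scale,
                      tx = t@tx * factor, ty = t@ty * factor,
                      levelMpp = t@levelMpp / factor)
}

#' Resample an image through a similarity transform
#'
#' Backward warping: output pixel q is sampled at t^{-1}(q), so image
#' content moves forward by `t` (a bright pixel at p ends up at
#' `transformPoints(p, t)`). Bilinear interpolation for intensity images,
#' out-of-bounds filled white (255).
#'
#' @param img a [SectionImage-class].
#' @param t a [SimilarityTransform2D-class].
#' @param outShape optional c(H, W) of the output; defaults to the input
#'   shape.
#' @return a [SectionImage-class] in the target frame.
#' @export
warpSimilarity <- function(img, t, outShape = NULL) {
  d <- dim(img@data)
  if (is.null(outShape)) outShape <- d[1:2]
  H <- outShape[1]; W <- outShape[2]
  ti <- invertTransform(t)
  gx <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  gy <- matrix(seq_len(H) - 1, H, W)
  src <- transformPoints(cbind(as.vector(gx), as.vector(gy)), ti)
  out <- array(0, c(H, W, 3L))
  vals <- bilinearSample(img@data, src[, 1], src[, 2], fill = 255)
  for (c in 1:3) out[, , c] <- matrix(vals[, c], H, W)
  SectionImage(out, mpp = img@mpp, offset = img@offset)
}

#' Resample a binary mask through a similarity transform
#'
#' Nearest-neighbour variant of [warpSimilarity()] (out-of-bounds filled 0).
#'
#' @param mask a [TissueMask-class].
#' @inheritParams warpSimilarity
#' @export
warpMaskSimilarity <- function(mask, t, outShape = NULL) {
  d <- dim(mask@mask)
  if (is.null(outShape)) outShape <- d
  H <- outShape[1]; W <- outShape[2]
  ti <- invertTransform(t)
  gx <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  gy <- matrix(seq_len(H) - 1, H, W)
  src <- transformPoints(cbind(as.vector(gx), as.vector(gy)), ti)
  vals <- nearestSample(mask@mask, src[, 1], src[, 2], fill = 0)
  TissueMask(matrix(vals, H, W), mpp = mask@mpp)
}
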
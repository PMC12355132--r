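# Boundary-driven non-rigid registration.
#
# The deformable stage never reads interior texture: the objective compares
# signed distance transforms of the ribbon *boundaries* only, under a cubic
# B-spline free-form deformation with a bending-energy penalty. Driving the
# field from the outline alone is what keeps glandular and nuclear
# morphology untouched inside the tissue.

#' BoundaryMask: filled ribbon mask, 1-px contour, and signed distances
#'
#' @slot mask binary matrix: largest connected component, holes filled.
#' @slot boundary binary matrix: 1-px outer contour of `mask`.
#' @slot sdt signed distance transform of the contour (px): negative
#'   inside the ribbon, positive outside, |sdt| = 0.5 on contour pixels.
#' @export
setClass("BoundaryMask",
  representation(mask = "matrix", boundary = "matrix", sdt = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@mask), dim(object@boundary)) ||
        !identical(dim(object@mask), dim(object@sdt)))
      return("mask/boundary/sdt shapes differ")
    TRUE
  })

setMethod("show", "BoundaryMask", function(object) {
  cat(sprintf("BoundaryMask %d x %d px, %d boundary px\n",
              ncol(object@mask), nrow(object@mask), sum(object@boundary)))
})

#' Union mask and bounding box of a rigidly aligned stack
#'
#' The rigidly aligned tissue masks are stacked into a single registration
#' mask; its tight half-open bounding box delimits the region extracted at
#' the high-resolution level for the non-rigid stage.
#'
#' @param rigidMasks list of co-registered [TissueMask-class] (same shape).
#' @return list(mask = [TissueMask-class] union, bbox = c(x0, y0, x1, y1)).
#' @export
buildRegistrationMask <- function(rigidMasks) {
  stopifnot(length(rigidMasks) >= 1L)
  u <- Reduce(function(a, b) pmax(a, b), lapply(rigidMasks, maskData))
  if (sum(u) == 0) stop("all masks empty: no tissue to register")
  rows <- which(rowSums(u) > 0); cols <- which(colSums(u) > 0)
  bbox <- c(min(cols) - 1, min(rows) - 1, max(cols), max(rows))
  list(mask = TissueMask(u, mpp = rigidMasks[[1]]@mpp), bbox = bbox)
}

#' Extract the ribbon boundary and its signed distance transform
#'
#' Keeps the largest connected component of the mask, fills its holes,
#' traces the 1-px outer contour, and computes the signed distance to that
#' contour (negative inside, positive outside).
#'
#' @param mask a [TissueMask-class].
#' @return a [BoundaryMask-class].
#' @export
extractBoundary <- function(mask) {
  m <- maskData(mask)
  if (sum(m) == 0) stop("empty mask: no boundary to extract")
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  comp <- (lab == keep) * 1
  comp <- EBImage::fillHull(comp)
  comp <- matrix(as.numeric(comp > 0), nrow(m), ncol(m))
  # inner contour: tissue pixels with a 4-neighbour outside (thin,
  # 8-connected staircase)
  er <- EBImage::erode(comp, EBImage::makeBrush(3, "diamond"))
  boundary <- comp - matrix(as.numeric(er > 0), nrow(m), ncol(m))
  dIn <- EBImage::distmap(comp)          # distance to background, inside
  dOut <- EBImage::distmap(1 - comp)     # distance to tissue, outside
  sdt <- matrix(0, nrow(m), ncol(m))
  inside <- comp > 0
  sdt[inside] <- -(as.numeric(dIn)[inside] - 0.5)
  sdt[!inside] <- as.numeric(dOut)[!inside] - 0.5
  new("BoundaryMask", mask = comp, boundary = boundary, sdt = sdt)
}

# Dense field from B-spline control grids: u = Bx Cu By', v = Bx Cv By'.
fieldFromGrid <- function(Cu, Cv, Bx, By, spacing) {
  displacementField(Bx %*% Cu %*% t(By), Bx %*% Cv %*% t(By),
                    gridSpacingPx = spacing)
}

#' Estimate a boundary-driven displacement field
#'
#' Fits a cubic B-spline free-form deformation (backward mapping) that
#' minimizes the mean squared difference between the fixed signed distance
#' transform and the moving one resampled through the field, plus a
#' bending-energy penalty on the control grid and a small ridge prior.
#' Solved by damped Gauss-Newton (Levenberg-Marquardt) on the control
#' points, accepting only improving steps (the objective trace is
#' non-increasing by construction); one multi-resolution halving
#' (spacing 2s then s).
#'
#' Only boundary-derived data (the signed distance transforms) enters the
#' objective; interior texture is never read.
#'
#' @param fixed,moving [BoundaryMask-class] objects of the same shape.
#' @param gridSpacingPx control-grid spacing (px).
#' @param nIterations gradient-descent iterations per resolution level.
#' @param bendingWeight weight of the bending-energy penalty.
#' @param l2Weight weight of a small ridge penalty on the control-point
#'   displacements themselves; damps the component of the field that the
#'   boundary cannot observe (slides tangential to the outline) instead of
#'   letting it drift.
#' @return a [DisplacementField-class] with attributes `converged`
#'   (logical) and `objectiveTrace` (numeric, non-increasing).
#' @export
estimateDisplacement <- function(fixed, moving, gridSpacingPx = 64L,
                                 nIterations = 15L, bendingWeight = 0.1,
                                 l2Weight = 0.002) {
  stopifnot(identical(dim(fixed@sdt), dim(moving@sdt)))
  H <- nrow(fixed@sdt); W <- ncol(fixed@sdt)
  if (nIterations == 0) {
    field <- displacementField(matrix(0, H, W), matrix(0, H, W),
                               gridSpacingPx = gridSpacingPx)
    attr(field, "converged") <- TRUE
    attr(field, "objectiveTrace") <- numeric(0)
    return(field)
  }
  # light smoothing knocks down mask-quantization jitter in the distances
  sdtF <- gaussianBlur(fixed@sdt, 1)
  sdtM <- gaussianBlur(moving@sdt, 1)
  gm <- imageGradients(sdtM)
  # band around the fixed boundary: where the distances carry signal
  wtsAll <- exp(-(sdtF / 8)^2)
  spacings <- c(gridSpacingPx * 2, gridSpacingPx)
  Cu <- Cv <- NULL
  trace <- numeric(0)
  stalled <- FALSE
  for (sp in spacings) {
    Bx <- bsplineBasis(H, sp); By <- bsplineBasis(W, sp)
    ncx <- ncol(Bx); ncy <- ncol(By)
    if (is.null(Cu)) {
      Cu <- Cv <- matrix(0, ncx, ncy)
    } else {            # carry the coarse-level field onto the finer grid
      prev <- fieldFromGrid(Cu, Cv, BxPrev, ByPrev, sp)
      Cu <- fitGridToField(prev@u, Bx, By)
      Cv <- fitGridToField(prev@v, Bx, By)
    }
    # band pixels, subsampled on a stride-2 lattice for speed
    sel <- which(wtsAll > 0.02)
    pyx <- arrayInd(sel, c(H, W))
    keep <- (pyx[, 1] %% 2L == 0L) & (pyx[, 2] %% 2L == 0L)
    pyx <- pyx[keep, , drop = FALSE]
    wp <- wtsAll[pyx]
    fp <- sdtF[pyx]
    BxB <- Bx[pyx[, 1], , drop = FALSE]
    ByB <- By[pyx[, 2], , drop = FALSE]
    iRep <- rep(seq_len(ncx), times = ncy)
    jRep <- rep(seq_len(ncy), each = ncx)
    Bprod <- BxB[, iRep, drop = FALSE] * ByB[, jRep, drop = FALSE]
    Hb <- bendingHessian(ncx, ncy) * bendingWeight / sp^2
    nC <- ncx * ncy
    ridge <- l2Weight / nC
    fieldAt <- function(Cu, Cv) {
      list(u = as.vector(Bprod %*% as.vector(Cu)),
           v = as.vector(Bprod %*% as.vector(Cv)))
    }
    objective <- function(Cu, Cv) {
      fv <- fieldAt(Cu, Cv)
      sx <- pyx[, 2] - 1 + fv$u; sy <- pyx[, 1] - 1 + fv$v
      r <- bilinearSample(sdtM, sx, sy, fill = max(sdtM))[, 1] - fp
      sum(wp * r^2) / sum(wp) +
        bendingWeight * (bendingEnergy(Cu) + bendingEnergy(Cv)) / sp^2 +
        l2Weight * (mean(Cu^2) + mean(Cv^2))
    }
    obj <- objective(Cu, Cv)
    lambda <- 1e-3
    for (it in seq_len(nIterations)) {
      fv <- fieldAt(Cu, Cv)
      sx <- pyx[, 2] - 1 + fv$u; sy <- pyx[, 1] - 1 + fv$v
      r <- bilinearSample(sdtM, sx, sy, fill = max(sdtM))[, 1] - fp
      gxv <- bilinearSample(gm$gx, sx, sy, fill = 0)[, 1]
      gyv <- bilinearSample(gm$gy, sx, sy, fill = 0)[, 1]
      wn <- wp / sum(wp)
      Ju <- Bprod * gxv
      Jv <- Bprod * gyv
      J <- cbind(Ju, Jv)
      A <- crossprod(J * wn, J)
      g <- crossprod(J, wn * r)
      # exact quadratic penalties (bending + ridge)
      A[seq_len(nC), seq_len(nC)] <- A[seq_len(nC), seq_len(nC)] + Hb + diag(ridge, nC)
      A[nC + seq_len(nC), nC + seq_len(nC)] <-
        A[nC + seq_len(nC), nC + seq_len(nC)] + Hb + diag(ridge, nC)
      g <- g + c(Hb %*% as.vector(Cu) + ridge * as.vector(Cu),
                 Hb %*% as.vector(Cv) + ridge * as.vector(Cv))
      accepted <- FALSE
      for (tries in 1:6) {
        delta <- tryCatch(
          solve(A + diag(lambda * max(diag(A)), 2L * nC), g),
          error = function(e) NULL)
        if (!is.null(delta)) {
          CuT <- Cu - matrix(delta[seq_len(nC)], ncx, ncy)
          CvT <- Cv - matrix(delta[nC + seq_len(nC)], ncx, ncy)
          objT <- objective(CuT, CvT)
          if (objT < obj) {
            Cu <- CuT; Cv <- CvT
            improvement <- (obj - objT) / max(obj, 1e-12)
            obj <- objT
            lambda <- max(lambda / 3, 1e-6)
            accepted <- TRUE
            break
          }
        }
        lambda <- lambda * 5
      }
      trace <- c(trace, obj)
      if (!accepted) { stalled <- TRUE; break }
      if (accepted && improvement < 1e-4) { stalled <- TRUE; break }
    }
    BxPrev <- Bx; ByPrev <- By
  }
  field <- fieldFromGrid(Cu, Cv, bsplineBasis(H, gridSpacingPx),
                         bsplineBasis(W, gridSpacingPx), gridSpacingPx)
  attr(field, "converged") <- stalled
  attr(field, "objectiveTrace") <- trace
  field
}

# exact Hessian of bendingEnergy(C) for vec(C) (column-major), i.e. of
# (||D2 rows||^2 + ||D2 cols||^2) / length(C)
bendingHessian <- function(ncx, ncy) {
  D2 <- function(n) {
    if (n < 3L) return(matrix(0, 0, n))
    D <- matrix(0, n - 2L, n)
    for (i in seq_len(n - 2L)) D[i, i:(i + 2L)] <- c(1, -2, 1)
    D
  }
  Dr <- D2(ncx); Dc <- D2(ncy)
  (kronecker(diag(ncy), crossprod(Dr)) +
     kronecker(crossprod(Dc), diag(ncx))) * 2 / (ncx * ncy)
}

# least-squares projection of a dense field onto a control grid
fitGridToField <- function(f, Bx, By) {
  # solve (Bx'Bx) C (By'By) = Bx' f By  (ridge-stabilized)
  Ax <- crossprod(Bx) + 1e-8 * diag(ncol(Bx))
  Ay <- crossprod(By) + 1e-8 * diag(ncol(By))
  solve(Ax, t(Bx) %*% f %*% By) %*% solve(Ay)
}


bendingEnergy <- function(C) {
  d2r <- diff(C, differences = 2)        # second differences along rows
  d2c <- t(diff(t(C), differences = 2))  # and columns
  (sum(d2r^2) + sum(d2c^2)) / length(C)
}



#' Perimeter of a ribbon boundary
#'
#' Chain-length estimate of the contour: straight and diagonal steps
#' between adjacent boundary pixels are weighted 0.948 and 1.343
#' (Kulpa's corner-corrected weights), which is nearly unbiased for
#' smooth shapes -- a rasterized disk of radius r measures ~2 pi r.
#'
#' @param bm a [BoundaryMask-class].
#' @return estimated contour length in pixels.
#' @export
boundaryLength <- function(bm) {
  b <- bm@boundary
  H <- nrow(b); W <- ncol(b)
  straight <- sum(b[, -W] * b[, -1]) + sum(b[-H, ] * b[-1, ])
  diagonal <- sum(b[-H, -W] * b[-1, -1]) + sum(b[-H, -1] * b[-1, -W])
  # a diagonal adjacency that shortcuts two straight ones is not a step
  0.948 * straight + 1.343 * diagonal
}

#' Apply a displacement field to a full-color image
#'
#' Backward resampling at (x + u, y + v): bilinear interpolation,
#' out-of-bounds filled white. The field found on the binary boundaries is
#' applied to the original non-binary image, so the stain texture is only
#' ever resampled once.
#'
#' @param img a [SectionImage-class].
#' @param field a [DisplacementField-class] matching the image shape.
#' @return the warped [SectionImage-class].
#' @export
warpDense <- function(img, field) {
  d <- dim(img@data)
  stopifnot(identical(dim(field@u), d[1:2]))
  H <- d[1]; W <- d[2]
  gx <- matrix(seq_len(W) - 1, H, W, byrow = TRUE) + field@u
  gy <- matrix(seq_len(H) - 1, H, W) + field@v
  vals <- bilinearSample(img@data, as.vector(gx), as.vector(gy), fill = 255)
  out <- array(0, c(H, W, 3L))
  for (c in 1:3) out[, , c] <- matrix(vals[, c], H, W)
  SectionImage(out, mpp = img@mpp, offset = img@offset)
}

#' Apply a displacement field to a binary mask
#'
#' Nearest-neighbour variant of [warpDense()] (out-of-bounds filled 0).
#'
#' @param mask a [TissueMask-class].
#' @param field a [DisplacementField-class].
#' @export
warpMaskDense <- function(mask, field) {
  m <- maskData(mask)
  stopifnot(identical(dim(field@u), dim(m)))
  H <- nrow(m); W <- ncol(m)
  gx <- matrix(seq_len(W) - 1, H, W, byrow = TRUE) + field@u
  gy <- matrix(seq_len(H) - 1, H, W) + field@v
  vals <- nearestSample(m, as.vector(gx), as.vector(gy), fill = 0)
  TissueMask(matrix(vals, H, W), mpp = mask@mpp)
}

#' Jacobian determinant of (identity + field)
#'
#' Morphology-preservation proxy: values far from 1 signal folding or
#' severe local expansion.
#'
#' @param field a [DisplacementField-class].
#' @return matrix of per-pixel Jacobian determinants.
#' @export
fieldJacobian <- function(field) {
  gu <- imageGradients(field@u)
  gv <- imageGradients(field@v)
  (1 + gu$gx) * (1 + gv$gy) - gu$gy * gv$gx
}
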
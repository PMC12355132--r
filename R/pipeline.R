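# End-to-end alignment pipeline: segmentation -> serial rigid ->
# boundary-driven non-rigid -> 2.5D core assembly.

#' Align a serial-section stack into a 2.5D core
#'
#' Runs the full morphology-preserving alignment chain: per-section tissue
#' masking, serial similarity registration against the first section,
#' boundary-driven non-rigid refinement (each section's ribbon boundary is
#' registered to its already-aligned predecessor's), and core assembly.
#' The non-rigid stage reads only ribbon boundaries, so interior gland and
#' nucleus morphology is preserved by construction.
#'
#' @param sections list of [SectionImage-class] (>= 2), one per ribbon, in
#'   z order.
#' @param hueWindow,closingRadiusPx forwarded to [computeTissueMask()].
#' @param maxKeypoints,ratio,inlierTolPx forwarded to the rigid stage.
#' @param gridSpacingPx,nIterations,bendingWeight forwarded to
#'   [estimateDisplacement()].
#' @param seed integer seed for the consensus sampling.
#' @param rigidOnly stop after the rigid stage.
#' @param rigidReport also score the rigid stage before non-rigid
#'   refinement (returned as `rigidReport`).
#' @return list with elements `core` ([Core25D-class]), `transforms`
#'   (rigid chain), `fields` (displacement fields; NULL when `rigidOnly`),
#'   `masks` (aligned per-section masks), and `report`
#'   ([RegistrationReport-class] scored on the final aligned sections).
#' @export
alignStack <- function(sections, hueWindow = "auto", closingRadiusPx = 5L,
                       maxKeypoints = 400L, ratio = 0.75, inlierTolPx = 3,
                       gridSpacingPx = 64L, nIterations = 15L,
                       bendingWeight = 0.1, seed = 1L, rigidOnly = FALSE,
                       rigidReport = FALSE) {
  Z <- length(sections)
  if (Z < 2L) stop("need at least 2 sections")
  mppv <- sections[[1]]@mpp
  masks <- lapply(sections, computeTissueMask, hueWindow = hueWindow,
                  closingRadiusPx = closingRadiusPx)
  transforms <- registerStackSerial(sections, masks,
                                    maxKeypoints = maxKeypoints,
                                    ratio = ratio, inlierTolPx = inlierTolPx,
                                    seed = seed)
  alignedImgs <- vector("list", Z)
  alignedMasks <- vector("list", Z)
  for (k in seq_len(Z)) {
    alignedImgs[[k]] <- if (k == 1L) sections[[k]] else
      warpSimilarity(sections[[k]], transforms[[k]])
    # ribbon masks are re-detected on the rigidly aligned rendering, not
    # resampled, so boundaries stay sub-pixel smooth for the next stage
    alignedMasks[[k]] <- if (k == 1L) masks[[k]] else
      computeTissueMask(alignedImgs[[k]], hueWindow = hueWindow,
                        closingRadiusPx = closingRadiusPx)
  }
  rigidRep <- NULL
  if (rigidReport && !rigidOnly)
    rigidRep <- stackRegistrationError(alignedImgs, alignedMasks, mpp = mppv,
                                       maxKeypoints = maxKeypoints,
                                       ratio = ratio)
  fields <- NULL
  if (!rigidOnly) {
    fields <- vector("list", Z)
    for (k in 2:Z) {
      fixed <- extractBoundary(alignedMasks[[k - 1]])
      moving <- extractBoundary(alignedMasks[[k]])
      fld <- estimateDisplacement(fixed, moving,
                                  gridSpacingPx = gridSpacingPx,
                                  nIterations = nIterations,
                                  bendingWeight = bendingWeight)
      alignedImgs[[k]] <- warpDense(alignedImgs[[k]], fld)
      alignedMasks[[k]] <- computeTissueMask(alignedImgs[[k]],
                                             hueWindow = hueWindow,
                                             closingRadiusPx = closingRadiusPx)
      fields[[k]] <- fld
    }
  }
  report <- stackRegistrationError(alignedImgs, alignedMasks, mpp = mppv,
                                   maxKeypoints = maxKeypoints, ratio = ratio)
  core <- assembleCore(alignedImgs, alignedMasks, mppv,
                       provenance = list(transforms = transforms,
                                         rigidOnly = rigidOnly, seed = seed))
  list(core = core, transforms = transforms, fields = fields,
       masks = alignedMasks, report = report, rigidReport = rigidRep)
}
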
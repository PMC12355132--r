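# Readers and writers: PNG sections and masks, JSON transform chains,
# TIFF displacement fields and core volumes, CSV reports and manifests.

#' Write / read a section image as PNG
#'
#' @param img a [SectionImage-class].
#' @param path output path (.png).
#' @export
writeSectionImage <- function(img, path) {
  png::writePNG(pmin(pmax(img@data, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname writeSectionImage
#' @param mpp microns per pixel to attach on read.
#' @export
readSectionImage <- function(path, mpp = 0.5) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  SectionImage(a[, , 1:3, drop = FALSE] * 255, mpp = mpp)
}

#' Write / read a tissue mask as single-channel PNG
#' @param mask a [TissueMask-class].
#' @param path output path (.png).
#' @export
writeMask <- function(mask, path) {
  png::writePNG(maskData(mask), path)
  invisible(path)
}

#' @rdname writeMask
#' @param mpp microns per pixel to attach on read.
#' @export
readMask <- function(path, mpp = 0.5) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  TissueMask((a > 0.5) * 1, mpp = mpp)
}

#' Serialize a rigid transform chain to JSON
#'
#' One record per section: angle in degrees, scale, translation in px,
#' the level's microns-per-pixel, and the link's match diagnostics.
#'
#' @param transforms list of [SimilarityTransform2D-class] (as returned
#'   by [registerStackSerial()], whose `pairStats` attribute is folded
#'   in).
#' @param path output path (.json).
#' @export
writeTransformChain <- function(transforms, path) {
  stats <- attr(transforms, "pairStats")
  recs <- lapply(seq_along(transforms), function(k) {
    t <- transforms[[k]]
    r <- list(section = k, theta_deg = t@theta * 180 / pi, scale = t@scale,
              tx = t@tx, ty = t@ty, level_mpp = t@levelMpp)
    if (!is.null(stats) && k >= 2L) {
      row <- stats[stats$pair == k - 1L, ]
      if (nrow(row) == 1L) {
        r$n_matches <- row$n_matches
        r$n_inliers <- row$n_inliers
      }
    }
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransformChain
#' @export
readTransformChain <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r)
    similarityTransform(theta = r$theta_deg * pi / 180, scale = r$scale,
                        tx = r$tx, ty = r$ty, levelMpp = r$level_mpp))
}

#' Write / read a displacement field as 2-channel 32-bit TIFF
#'
#' u and v (px) are stored as two float TIFF pages plus a JSON sidecar
#' with the control-grid spacing, convergence flag, and final objective.
#'
#' @param field a [DisplacementField-class].
#' @param path output path (.tif); the sidecar gets `.json` appended.
#' @export
writeDisplacementField <- function(field, path) {
  # float TIFF samples must lie in [0, 1]: store (d / (2 s) + 1/2) and
  # keep the scale s in the sidecar
  s <- max(abs(field@u), abs(field@v), 1e-9)
  tiff::writeTIFF(list(field@u / (2 * s) + 0.5, field@v / (2 * s) + 0.5),
                  path, bits.per.sample = 32L, reduce = FALSE)
  trace <- attr(field, "objectiveTrace")
  jsonlite::write_json(list(grid_spacing_px = field@gridSpacingPx,
                            scale_px = s,
                            converged = isTRUE(attr(field, "converged")),
                            final_objective = if (length(trace)) trace[length(trace)] else NA),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDisplacementField
#' @export
readDisplacementField <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  s <- meta$scale_px
  displacementField((pages[[1]] - 0.5) * 2 * s, (pages[[2]] - 0.5) * 2 * s,
                    gridSpacingPx = meta$grid_spacing_px)
}

#' Write a phantom stack to disk
#'
#' Numbered PNG sections, per-section truth masks and landmark CSVs, and
#' a JSON sidecar with the ground-truth transforms as
#' {theta_deg, scale, tx, ty}.
#'
#' @param stack a [PhantomStack-class].
#' @param dir output directory (created if missing).
#' @export
writePhantomStack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Z <- nSections(stack)
  for (k in seq_len(Z)) {
    writeSectionImage(stack@sections[[k]],
                      file.path(dir, sprintf("section_%02d.png", k)))
    writeMask(TissueMask(stack@tissueTruth[[k]]),
              file.path(dir, sprintf("truth_mask_%02d.png", k)))
    lm <- stack@landmarks[[k]]
    utils::write.csv(data.frame(x = lm[, 1], y = lm[, 2]),
                     file.path(dir, sprintf("landmarks_%02d.csv", k)),
                     row.names = FALSE)
  }
  truth <- lapply(seq_len(Z), function(k) {
    t <- stack@trueTransforms[[k]]
    list(section = k, theta_deg = t@theta * 180 / pi, scale = t@scale,
         tx = t@tx, ty = t@ty)
  })
  jsonlite::write_json(truth, file.path(dir, "truth_transforms.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a registration report as CSV + JSON
#' @param report a [RegistrationReport-class].
#' @param prefix output path prefix (writes `<prefix>.csv` and
#'   `<prefix>.json`).
#' @export
writeRegistrationReport <- function(report, prefix) {
  utils::write.csv(report@perPair, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(core_error_um = report@coreErrorUm,
                            per_pair = report@perPair),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Write a 2.5D core volume
#'
#' Sections as a multi-page TIFF, masks as PNGs, metadata as JSON.
#'
#' @param core a [Core25D-class].
#' @param dir output directory.
#' @export
writeCore25D <- function(core, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(core@volume, function(s) pmin(pmax(s@data, 0), 255) / 255)
  tiff::writeTIFF(pages, file.path(dir, "core.tif"), bits.per.sample = 8L)
  for (k in seq_along(core@masks))
    writeMask(core@masks[[k]], file.path(dir, sprintf("mask_%02d.png", k)))
  jsonlite::write_json(list(z = coreDepth(core), mpp = core@mpp),
                       file.path(dir, "core.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeCore25D
#' @export
readCore25D <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "core.json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "core.tif"), all = TRUE)
  vol <- lapply(pages, function(p) SectionImage(p[, , 1:3] * 255, mpp = meta$mpp))
  masks <- lapply(seq_len(meta$z), function(k)
    readMask(file.path(dir, sprintf("mask_%02d.png", k)), mpp = meta$mpp))
  assembleCore(vol, masks, meta$mpp)
}

#' Write extracted 2.5D patches
#'
#' Each patch becomes one multi-page TIFF (one page per depth slice); a
#' manifest CSV records origin and tissue fraction.
#'
#' @param patches list of [Patch25D-class].
#' @param dir output directory.
#' @export
writePatches <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(patches, function(p) {
    name <- sprintf("patch_%05d_%05d.tif", p@origin[1], p@origin[2])
    pages <- lapply(seq_len(dim(p@data)[1]), function(t)
      pmin(pmax(p@data[t, , , ], 0), 255) / 255)
    tiff::writeTIFF(pages, file.path(dir, name), bits.per.sample = 8L)
    data.frame(file = name, origin_x = p@origin[1], origin_y = p@origin[2],
               tissue_fraction = p@tissueFraction)
  })
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(manifest))
    manifest <- data.frame(file = character(0), origin_x = numeric(0),
                           origin_y = numeric(0), tissue_fraction = numeric(0))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Save / load a run configuration
#'
#' YAML round trip: `loadRunConfig(saveRunConfig(cfg, path))` returns an
#' identical configuration. Every pipeline command echoes its fully
#' resolved configuration next to its outputs.
#'
#' @param config named list of settings.
#' @param path output path (.yaml).
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname saveRunConfig
#' @export
loadRunConfig <- function(path) yaml::read_yaml(path)
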
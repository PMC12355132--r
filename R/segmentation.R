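# Tissue masking and ribbon extraction.

#' RibbonComponent: one connected tissue ribbon in a section
#'
#' @slot labelId integer component label.
#' @slot mask binary matrix covering the full image (this component only).
#' @slot bbox half-open 0-based pixel box c(x0, y0, x1, y1).
#' @slot areaPx number of pixels in the component.
#' @export
setClass("RibbonComponent",
  representation(labelId = "integer", mask = "matrix", bbox = "numeric",
                 areaPx = "integer"),
  validity = function(object) {
    if (object@areaPx != sum(object@mask)) return("areaPx != sum(mask)")
    TRUE
  })

setMethod("show", "RibbonComponent", function(object) {
  cat(sprintf("RibbonComponent #%d, %d px, bbox [%g,%g)x[%g,%g)\n",
              object@labelId, object@areaPx, object@bbox[1], object@bbox[3],
              object@bbox[2], object@bbox[4]))
})

# Otsu threshold on a numeric vector in [0, 1].
otsuThreshold <- function(x, nbins = 256L) {
  h <- tabulate(pmin(pmax(floor(x * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  muT <- mu[nbins]
  sigma <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma[!is.finite(sigma)] <- -Inf
  (which.max(sigma)) / nbins
}

#' Compute a tissue mask by hue thresholding
#'
#' Converts the RGB section to HSV and keeps pixels whose hue falls in the
#' stain window, then applies one morphological closing with a disk to fill
#' small gaps (nucleus-scale holes left by the threshold). Near-white
#' pixels (saturation <= 0.05) are always background.
#'
#' With `hueWindow = "auto"` the threshold is Otsu's split of the hue
#' histogram restricted to non-white pixels, and the foreground is the
#' majority side of the split (the dominant stain hue); an explicit
#' length-2 hue window in [0, 1] overrides.
#'
#' @param img a [SectionImage-class].
#' @param hueWindow `"auto"` or numeric c(lo, hi) hue interval.
#' @param closingRadiusPx disk radius of the single closing pass.
#' @return a [TissueMask-class].
#' @export
computeTissueMask <- function(img, hueWindow = "auto", closingRadiusPx = 5L) {
  d <- dim(img@data)
  if (d[1] < 1 || d[2] < 1) stop("zero-size image")
  dat <- pmin(pmax(img@data, 0), 255)   # guard against interpolation round-off
  rgb <- rbind(as.vector(dat[, , 1]), as.vector(dat[, , 2]),
               as.vector(dat[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  hue <- hsv[1, ]; sat <- hsv[2, ]
  cand <- sat > 0.05
  fg <- logical(length(hue))
  if (identical(hueWindow, "auto")) {
    if (any(cand)) {
      th <- otsuThreshold(hue[cand])
      hi <- hue >= th
      majorityHigh <- mean(hi[cand]) >= 0.5
      fg <- cand & (if (majorityHigh) hi else !hi)
    }
  } else {
    stopifnot(length(hueWindow) == 2L)
    fg <- cand & hue >= hueWindow[1] & hue <= hueWindow[2]
  }
  m <- matrix(as.numeric(fg), d[1], d[2])
  if (closingRadiusPx > 0 && sum(m) > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closingRadiusPx) + 1L, "disc")
    m <- matrix(as.numeric(EBImage::closing(m, brush) > 0), d[1], d[2])
  }
  TissueMask(m, mpp = img@mpp)
}

# 8-connected labeling: EBImage::bwlabel components merged across
# diagonal adjacencies with a union-find pass.
label8 <- function(m) {
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  H <- nrow(lab); W <- ncol(lab)
  shifts <- list(c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    r1 <- if (s[1] > 0) 1:(H - 1) else 2:H
    r2 <- r1 + s[1]
    c1 <- if (s[2] > 0) 1:(W - 1) else 2:W
    c2 <- c1 + s[2]
    a <- lab[r1, c1]; b <- lab[r2, c2]
    touch <- which(a > 0 & b > 0 & a != b)
    if (length(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (k in seq_len(nrow(pairs))) unite(pairs[k, 1], pairs[k, 2])
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Label individual tissue ribbons
#'
#' Connected components (8-connectivity) of the tissue mask with area at
#' least `minAreaPx`, in a stable geometric order: by bounding-box top
#' coordinate, then left coordinate.
#'
#' @param mask a [TissueMask-class].
#' @param minAreaPx minimum component area in pixels; the default rejects
#'   specks below 0.1% of the image area.
#' @return list of [RibbonComponent-class] (empty for an empty mask).
#' @export
labelRibbons <- function(mask, minAreaPx = NULL) {
  m <- maskData(mask)
  if (is.null(minAreaPx)) minAreaPx <- ceiling(0.001 * length(m))
  if (sum(m) == 0) return(list())
  lab <- label8(m)
  n <- max(lab)
  comps <- list()
  for (k in seq_len(n)) {
    sel <- lab == k
    area <- sum(sel)
    if (area < minAreaPx) next
    rows <- which(rowSums(sel) > 0); cols <- which(colSums(sel) > 0)
    comps[[length(comps) + 1L]] <- new("RibbonComponent",
      labelId = as.integer(k), mask = matrix(as.numeric(sel), nrow(m), ncol(m)),
      bbox = c(min(cols) - 1, min(rows) - 1, max(cols), max(rows)),
      areaPx = as.integer(area))
  }
  ord <- order(vapply(comps, function(c) c@bbox[2], 1),
               vapply(comps, function(c) c@bbox[1], 1))
  comps[ord]
}

#' Crop one ribbon out of its parent section
#'
#' Returns the ribbon's padded bounding-box crop, clamped to the image
#' bounds, with the crop offset recorded in the result's `offset` slot so
#' coordinates map back to the parent image.
#'
#' @param img a [SectionImage-class].
#' @param ribbon a [RibbonComponent-class].
#' @param padPx padding added on every side before clamping.
#' @return a [SectionImage-class] crop.
#' @export
cropRibbon <- function(img, ribbon, padPx = 0L) {
  d <- dim(img@data)
  b <- ribbon@bbox
  x0 <- max(0, b[1] - padPx); y0 <- max(0, b[2] - padPx)
  x1 <- min(d[2], b[3] + padPx); y1 <- min(d[1], b[4] + padPx)
  crop <- img@data[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  SectionImage(crop, mpp = img@mpp, offset = img@offset + c(x0, y0))
}
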
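# Shared numerical helpers. Conventions used package-wide:
#   * images are arrays indexed [row = y, col = x (, channel)], intensities
#     in [0, 255];
#   * point coordinates are 0-based with x = column (rightward) and
#     y = row (downward); pixel (i, j) in R's 1-based indexing sits at
#     (x, y) = (j - 1, i - 1);
#   * bounding boxes (x0, y0, x1, y1) are half-open.

#' Sample an image at fractional coordinates
#'
#' Bilinear interpolation at 0-based coordinates. Out-of-bounds samples
#' return `fill`.
#'
#' @param img matrix or H x W x C array.
#' @param x,y numeric vectors of 0-based coordinates (x = column).
#' @param fill scalar fill value for out-of-bounds samples.
#' @return a length(x) x C matrix (C = 1 for a matrix input).
#' @keywords internal
bilinearSample <- function(img, x, y, fill = 255) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  C <- if (length(d) == 3L) d[3] else 1L
  if (length(d) == 2L) dim(img) <- c(H, W, 1L)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- matrix(fill, length(x), C)
  # corners clamped; validity tracked separately so borders interpolate
  ok <- x >= -0.5 & x <= W - 0.5 & y >= -0.5 & y <= H - 0.5
  cx0 <- pmin(pmax(x0, 0), W - 1); cx1 <- pmin(cx0 + 1, W - 1)
  cy0 <- pmin(pmax(y0, 0), H - 1); cy1 <- pmin(cy0 + 1, H - 1)
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  for (c in seq_len(C)) {
    plane <- img[, , c]
    v <- w00 * plane[cbind(cy0 + 1, cx0 + 1)] +
         w10 * plane[cbind(cy0 + 1, cx1 + 1)] +
         w01 * plane[cbind(cy1 + 1, cx0 + 1)] +
         w11 * plane[cbind(cy1 + 1, cx1 + 1)]
    out[ok, c] <- v[ok]
  }
  out
}

#' Nearest-neighbour sampling (masks)
#' @inheritParams bilinearSample
#' @keywords internal
nearestSample <- function(img, x, y, fill = 0) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  xi <- round(x); yi <- round(y)
  ok <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
  out <- rep(fill, length(x))
  out[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
  out
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Separable Gaussian blur with replicated borders.
gaussianBlur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  padConv <- function(m, kv, dim) {
    n <- length(kv); half <- (n - 1L) / 2L
    if (dim == 1L) {
      mp <- rbind(m[rep(1L, half), , drop = FALSE], m,
                  m[rep(nrow(m), half), , drop = FALSE])
      out <- matrix(0, nrow(m), ncol(m))
      for (i in seq_len(n)) out <- out + kv[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    } else {
      mp <- cbind(m[, rep(1L, half), drop = FALSE], m,
                  m[, rep(ncol(m), half), drop = FALSE])
      out <- matrix(0, nrow(m), ncol(m))
      for (i in seq_len(n)) out <- out + kv[i] * mp[, i:(i + ncol(m) - 1L), drop = FALSE]
    }
    out
  }
  padConv(padConv(mat, k, 1L), k, 2L)
}

# Central-difference gradients of a matrix; replicated borders.
imageGradients <- function(mat) {
  H <- nrow(mat); W <- ncol(mat)
  gx <- (mat[, c(2:W, W)] - mat[, c(1, 1:(W - 1))]) / 2
  gy <- (mat[c(2:H, H), ] - mat[c(1, 1:(H - 1)), ]) / 2
  list(gx = gx, gy = gy)
}

# Cubic B-spline kernel, support (-2, 2).
bspline3 <- function(t) {
  at <- abs(t)
  ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
         ifelse(at < 2, (2 - at)^3 / 6, 0))
}

# Pixel->control-point cubic B-spline basis matrix for one axis.
# Control point i (1-based) sits at coordinate (i - 2) * spacing, so the
# grid overhangs the image by one spacing on each side.
bsplineBasis <- function(n_pixels, spacing) {
  nc <- ceiling((n_pixels - 1) / spacing) + 3L
  px <- (seq_len(n_pixels) - 1) / spacing        # in control-grid units
  ci <- seq_len(nc) - 2L
  B <- outer(px, ci, function(p, i) bspline3(p - i))
  B
}

# 3x3 maximum filter (replicated borders)
maxFilter3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    rows <- pmin(pmax(seq_len(H) + dy, 1L), H)
    cols <- pmin(pmax(seq_len(W) + dx, 1L), W)
    out <- pmax(out, m[rows, cols])
  }
  out
}

rmsd <- function(a, b) sqrt(mean((a - b)^2))

stopifnotFinite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(TRUE)
}
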
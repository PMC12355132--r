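# Shared phantom fixtures, built once per test run and cached.
.phantomCache <- new.env(parent = emptyenv())

testPhantom <- function(seed = 7, nSections = 4, warpAmplitude = 0,
                        noiseSd = 3, canvasSize = 384) {
  key <- paste(seed, nSections, warpAmplitude, noiseSd, canvasSize, sep = "_")
  if (is.null(.phantomCache[[key]])) {
    .phantomCache[[key]] <- generatePhantomCore(phantomSpec(
      nSections = nSections, canvasSize = canvasSize,
      warpAmplitude = warpAmplitude, noiseSd = noiseSd, seed = seed))
  }
  .phantomCache[[key]]
}

testMasks <- function(ph) {
  key <- paste0("masks_", format(sum(ph@sections[[1]]@data)), "_", nSections(ph))
  if (is.null(.phantomCache[[key]]))
    .phantomCache[[key]] <- lapply(ph@sections, computeTissueMask)
  .phantomCache[[key]]
}

# angles wrapped to (-pi, pi] for transform comparisons
angDiff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d)
}

transformClose <- function(t1, t2, tolDeg = 0.5, tolScale = 0.01, tolPx = 1) {
  angDiff(t1@theta, t2@theta) * 180 / pi <= tolDeg &&
    abs(t1@scale - t2@scale) <= tolScale &&
    abs(t1@tx - t2@tx) <= tolPx && abs(t1@ty - t2@ty) <= tolPx
}
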
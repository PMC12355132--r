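# Momentum self-distillation for the 2.5D encoder.
#
# A student network matches the probability distribution of a momentum
# ("teacher") copy of itself: global crops of a 2.5D patch feed the
# teacher, all crops feed the student, and the student minimizes the
# cross-entropy between the teacher's centered, sharpened distribution
# and its own. The teacher is never trained directly -- it is an
# exponential moving average of the student -- and the running center
# keeps the teacher's logits from collapsing to one mode. At this desk
# scale the trainable part of the student is the projection head; the
# shared encoder trunk is carried along in the EMA identically.

#' Create a distillation state
#'
#' @param cfg an [encoderConfig()] for the shared trunk.
#' @param K output dimension of the projection head.
#' @param seed seed for head initialization.
#' @return list with `student` and `teacher` parameter sets (trunk +
#'   head), and a zero `center` vector.
#' @export
distillInit <- function(cfg, K = 16L, seed = 1L) {
  trunk <- initEncoder(cfg)
  head <- withSeed(seed + 1L, {
    list(Wh = matrix(stats::rnorm(K * cfg$D, sd = 0.2), K, cfg$D),
         bh = rep(0, K))
  })
  student <- list(trunk = trunk, head = head)
  list(student = student, teacher = student, center = rep(0, K), cfg = cfg)
}

headLogits <- function(params, cfg, view) {
  emb <- encodePatch(view$patch, cfg, params$trunk,
                     tileOffset = view$tileOffset,
                     fullTilesWH = view$fullTilesWH)$clsEmbedding
  list(logits = as.vector(params$head$Wh %*% emb) + params$head$bh, emb = emb)
}

softmaxVec <- function(x) { e <- exp(x - max(x)); e / sum(e) }

# elementwise EMA over an arbitrarily nested parameter list
emaUpdate <- function(teacher, student, m) {
  if (is.list(teacher)) {
    out <- teacher
    for (nm in seq_along(teacher)) out[[nm]] <- emaUpdate(teacher[[nm]], student[[nm]], m)
    return(out)
  }
  m * teacher + (1 - m) * student
}

#' One momentum self-distillation step
#'
#' Computes the distillation loss -- the mean cross-entropy between the
#' teacher's distribution on each global view (centered, temperature
#' `tauT`) and the student's distribution on every other view
#' (temperature `tauS`) -- takes one SGD step on the student's projection
#' head (analytic gradient), then updates the teacher as an elementwise
#' exponential moving average of the student with momentum `m`, and the
#' center with momentum `centerM`.
#'
#' @param state a [distillInit()] state.
#' @param globalViews,localViews lists of views; each view is
#'   list(patch, tileOffset, fullTilesWH) as accepted by [encodePatch()].
#' @param m teacher momentum in [0, 1] (1 freezes the teacher, 0 copies
#'   the student).
#' @param tauS,tauT student and teacher softmax temperatures (> 0).
#' @param centerM center momentum in [0, 1].
#' @param lr learning rate of the student head.
#' @return the updated state, with the step's `loss` attached.
#' @export
distillStep <- function(state, globalViews, localViews, m = 0.996,
                        tauS = 0.1, tauT = 0.04, centerM = 0.9, lr = 0.1) {
  if (tauS <= 0 || tauT <= 0) stop("temperatures must be > 0")
  if (m < 0 || m > 1 || centerM < 0 || centerM > 1)
    stop("momenta must lie in [0, 1]")
  cfg <- state$cfg
  views <- c(globalViews, localViews)
  nGlobal <- length(globalViews)
  tOut <- lapply(globalViews, function(v) headLogits(state$teacher, cfg, v))
  sOut <- lapply(views, function(v) headLogits(state$student, cfg, v))
  K <- length(state$center)
  loss <- 0; nPairs <- 0
  gW <- matrix(0, K, cfg$D); gb <- rep(0, K)
  for (g in seq_len(nGlobal)) {
    pT <- softmaxVec((tOut[[g]]$logits - state$center) / tauT)
    for (v in seq_along(views)) {
      if (v == g) next
      zS <- sOut[[v]]$logits / tauS
      pS <- softmaxVec(zS)
      loss <- loss + (-sum(pT * (zS - max(zS) - log(sum(exp(zS - max(zS)))))))
      dz <- (pS - pT) / tauS
      gW <- gW + outer(dz, sOut[[v]]$emb)
      gb <- gb + dz
      nPairs <- nPairs + 1
    }
  }
  loss <- loss / nPairs
  state$student$head$Wh <- state$student$head$Wh - lr * gW / nPairs
  state$student$head$bh <- state$student$head$bh - lr * gb / nPairs
  state$teacher <- emaUpdate(state$teacher, state$student, m)
  tLogits <- vapply(tOut, function(o) o$logits, numeric(K))
  state$center <- centerM * state$center +
    (1 - centerM) * rowMeans(matrix(tLogits, nrow = K))
  state$loss <- loss
  state
}

#' Build global and local views of a 2.5D patch
#'
#' Global views cover the full spatial extent; local views crop a smaller
#' tile window (full depth is always kept, since depth is the signal the
#' encoder is built for). Crops are tile-aligned so positional rows stay
#' meaningful.
#'
#' @param patch F x H x W x 3 array matching `cfg`.
#' @param cfg an [encoderConfig()].
#' @param nLocal number of local views.
#' @param localTiles spatial size of a local view, in tiles per side.
#' @return list(global = ..., local = ...) of view lists.
#' @export
makeViews <- function(patch, cfg, nLocal = 4L, localTiles = 1L) {
  tilesY <- cfg$H %/% cfg$P; tilesX <- cfg$W %/% cfg$P
  full <- c(tilesY, tilesX)
  global <- list(
    list(patch = patch, tileOffset = c(0L, 0L), fullTilesWH = full),
    # second global view: light photometric jitter, same geometry
    list(patch = patch + array(stats::rnorm(length(patch), sd = 2), dim(patch)),
         tileOffset = c(0L, 0L), fullTilesWH = full))
  local <- lapply(seq_len(nLocal), function(i) {
    oy <- sample.int(tilesY - localTiles + 1L, 1L) - 1L
    ox <- sample.int(tilesX - localTiles + 1L, 1L) - 1L
    sub <- patch[, (oy * cfg$P + 1):((oy + localTiles) * cfg$P),
                 (ox * cfg$P + 1):((ox + localTiles) * cfg$P), , drop = FALSE]
    list(patch = sub, tileOffset = c(oy, ox), fullTilesWH = full)
  })
  list(global = global, local = local)
}
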
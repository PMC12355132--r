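# Combined space-time attention and rollout attribution.

#' Combine spatial and depth attention into one token-to-token matrix
#'
#' For divided attention, token (i, j) reaches token (p, q) through a
#' unique path: depth attention carries (p, j) -> (p, q) with weight
#' `T[p, j, q]`, and spatial attention carries (i, j) -> (p, j) with
#' weight `S[i, j, p]`. The combined weight is the product
#' `W[(i, j), (p, q)] = S[i, j, p] * T[p, j, q]`, arranged as an
#' (N F) x (N F) matrix over patch tokens with flat index
#' (t - 1) N + p. Rows sum to one because each factor is row-stochastic.
#'
#' @param S N x F x N array of spatial weights (row-stochastic over the
#'   last index).
#' @param T N x F x F array of depth weights (row-stochastic over the
#'   last index).
#' @param tol tolerance for validating row-stochasticity.
#' @return (N F) x (N F) row-stochastic matrix.
#' @export
combineSpaceTime <- function(S, T, tol = 1e-6) {
  N <- dim(S)[1]; Fv <- dim(S)[2]
  stopifnot(dim(S)[3] == N, all(dim(T) == c(N, Fv, Fv)))
  if (max(abs(apply(S, c(1, 2), sum) - 1)) > tol)
    stop("S rows must sum to 1 over the target spatial index")
  if (max(abs(apply(T, c(1, 2), sum) - 1)) > tol)
    stop("T rows must sum to 1 over the target depth index")
  W <- matrix(0, N * Fv, N * Fv)
  for (i in seq_len(N)) for (j in seq_len(Fv)) {
    row <- (j - 1L) * N + i
    for (p in seq_len(N)) {
      W[row, (seq_len(Fv) - 1L) * N + p] <- S[i, j, p] * T[p, j, ]
    }
  }
  W
}

#' Attention rollout across layers
#'
#' Attribution of every token to the input tokens, computed by
#' recursively multiplying the per-layer combined attention matrices from
#' the input layer upward: R_l = W_l R_{l-1}. The product of
#' row-stochastic matrices is row-stochastic, so each row of the result
#' is a distribution over input tokens.
#'
#' @param perLayerW list of (N F) x (N F) row-stochastic matrices, input
#'   layer first.
#' @param withResidual if TRUE, each layer matrix is averaged with the
#'   identity before multiplying (models the residual path; off by
#'   default since the combined-attention definition has no identity
#'   term).
#' @return the (N F) x (N F) attribution matrix.
#' @export
attentionRollout <- function(perLayerW, withResidual = FALSE) {
  stopifnot(length(perLayerW) >= 1L)
  n <- nrow(perLayerW[[1]])
  R <- NULL
  for (W in perLayerW) {
    if (!is.matrix(W) || nrow(W) != n || ncol(W) != n)
      stop("all layer matrices must be square and of equal dimension")
    if (withResidual) W <- (W + diag(n)) / 2
    R <- if (is.null(R)) W else W %*% R
  }
  R
}

#' Per-slice attribution heat maps from a rollout row
#'
#' Reshapes one row of the rollout attribution into F heat maps of the
#' spatial tile grid, for overlay on the 2.5D patch (highest attention =
#' hottest).
#'
#' @param attribution a length-(N F) attribution row.
#' @param tilesY,tilesX spatial tile grid of one slice.
#' @param F number of depth slices.
#' @return list of F tilesY x tilesX matrices.
#' @export
attributionMaps <- function(attribution, tilesY, tilesX, F) {
  N <- tilesY * tilesX
  stopifnot(length(attribution) == N * F)
  lapply(seq_len(F), function(t) {
    v <- attribution[(t - 1L) * N + seq_len(N)]
    matrix(v, tilesY, tilesX, byrow = TRUE)
  })
}
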
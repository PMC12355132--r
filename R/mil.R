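# Attention-based multiple-instance learning for core-level grading.
#
# A core is a "bag" of 2.5D patch feature vectors. A gated attention
# module (tanh x sigmoid) scores every instance, softmax turns the scores
# into weights, and the weighted feature sum feeds a linear classifier.
# The whole model is small enough that gradients are written out by hand.

GG_LEVELS <- c("BN", "GG1", "GG2", "GG3", "GG4/5")

#' FeatureBag: instances of one core plus its grade-group label
#'
#' @slot instances K x D matrix of per-patch feature vectors.
#' @slot coreId core identifier.
#' @slot label grade group, one of BN, GG1, GG2, GG3, GG4/5 (or NA).
#' @export
setClass("FeatureBag",
  representation(instances = "matrix", coreId = "character",
                 label = "character"),
  validity = function(object) {
    if (nrow(object@instances) < 1L) return("a bag needs at least 1 instance")
    if (!all(is.finite(object@instances))) return("non-finite features")
    if (!is.na(object@label) && !(object@label %in% GG_LEVELS))
      return("label must be one of BN, GG1, GG2, GG3, GG4/5")
    TRUE
  })

#' Construct a FeatureBag
#' @param instances K x D feature matrix.
#' @param coreId identifier string.
#' @param label grade-group label (optional).
#' @export
featureBag <- function(instances, coreId = "core", label = NA_character_) {
  new("FeatureBag", instances = rbind(instances), coreId = coreId,
      label = as.character(label))
}

setMethod("show", "FeatureBag", function(object) {
  cat(sprintf("FeatureBag '%s': %d instances x %d features, label %s\n",
              object@coreId, nrow(object@instances), ncol(object@instances),
              object@label))
})

#' Initialize gated-attention MIL parameters
#'
#' @param D feature dimension.
#' @param nClasses number of output classes.
#' @param hidden attention hidden dimension.
#' @param seed seed for initialization.
#' @return parameter list (V, U, w for the gated attention; C, b for the
#'   classifier).
#' @export
abmilInit <- function(D, nClasses = 5L, hidden = 128L, seed = 1L) {
  withSeed(seed, {
    list(V = matrix(stats::rnorm(hidden * D, sd = 0.1), hidden, D),
         U = matrix(stats::rnorm(hidden * D, sd = 0.1), hidden, D),
         w = stats::rnorm(hidden, sd = 0.1),
         C = matrix(stats::rnorm(nClasses * D, sd = 0.1), nClasses, D),
         b = rep(0, nClasses))
  })
}

#' Pool a bag with gated attention and classify
#'
#' Instance scores a_k = w' (tanh(V h_k) * sigmoid(U h_k)) are softmaxed
#' over the bag into attention weights; the attention-weighted feature sum
#' goes through the linear classifier. Deterministic given parameters,
#' and invariant to instance order.
#'
#' @param bag a [featureBag()].
#' @param params an [abmilInit()] parameter list.
#' @return list(classProbs, attention, predictedClass, logits).
#' @export
abmilPool <- function(bag, params) {
  H <- bag@instances
  if (nrow(H) == 0L) stop("empty bag")
  hv <- tanh(H %*% t(params$V))
  hu <- 1 / (1 + exp(-(H %*% t(params$U))))
  a <- as.vector((hv * hu) %*% params$w)
  a <- a - max(a)
  al <- exp(a) / sum(exp(a))
  z <- as.vector(al %*% H)
  logits <- as.vector(params$C %*% z) + params$b
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  names(probs) <- rownames(params$C)
  list(classProbs = probs, attention = al,
       predictedClass = which.max(probs), logits = logits)
}

# analytic gradient of the cross-entropy loss of one bag
abmilGrad <- function(bag, params, label) {
  H <- bag@instances
  K <- nrow(H)
  zv <- H %*% t(params$V); zu <- H %*% t(params$U)
  hv <- tanh(zv); hu <- 1 / (1 + exp(-zu))
  g <- hv * hu                       # K x hidden
  a <- as.vector(g %*% params$w)
  am <- a - max(a)
  al <- exp(am) / sum(exp(am))
  z <- as.vector(al %*% H)
  logits <- as.vector(params$C %*% z) + params$b
  e <- exp(logits - max(logits)); p <- e / sum(e)
  y <- rep(0, length(p)); y[label] <- 1
  loss <- -log(max(p[label], 1e-12))
  dlog <- p - y
  gC <- outer(dlog, z)
  gb <- dlog
  dz <- as.vector(t(params$C) %*% dlog)           # D
  dal <- as.vector(H %*% dz)                      # K
  da <- al * (dal - sum(dal * al))                # softmax jacobian
  dg <- outer(da, params$w)                       # K x hidden
  gw <- as.vector(t(g) %*% da)
  dzv <- dg * hu * (1 - hv^2)
  dzu <- dg * hv * hu * (1 - hu)
  gV <- t(dzv) %*% H
  gU <- t(dzu) %*% H
  list(loss = loss, V = gV, U = gU, w = gw, C = gC, b = gb)
}

#' Train a small ABMIL model
#'
#' Full-batch gradient descent with cross-entropy loss, light weight
#' decay, and early stopping on a held-out validation split (the
#' parameters with the best validation loss are returned). Provided for
#' the synthetic demonstration task, not for production-scale training.
#'
#' @param bags list of labelled [featureBag()]s.
#' @param labels integer class labels (1-based).
#' @param nClasses number of classes.
#' @param hidden attention hidden dimension.
#' @param epochs gradient steps.
#' @param lr learning rate.
#' @param weightDecay L2 penalty on all weights.
#' @param valFraction fraction of bags held out for early stopping (the
#'   tail of the list; 0 disables).
#' @param seed initialization seed.
#' @return list(params, lossTrace, valTrace, bestEpoch).
#' @export
trainAbmil <- function(bags, labels, nClasses = 2L, hidden = 32L,
                       epochs = 150L, lr = 0.5, weightDecay = 1e-3,
                       valFraction = 0.15, seed = 1L) {
  D <- ncol(bags[[1]]@instances)
  nVal <- floor(valFraction * length(bags))
  valIdx <- if (nVal > 0) tail(seq_along(bags), nVal) else integer(0)
  trIdx <- setdiff(seq_along(bags), valIdx)
  params <- abmilInit(D, nClasses, hidden, seed)
  trace <- valTrace <- numeric(epochs)
  best <- params; bestVal <- Inf; bestEpoch <- 0L
  bagLoss <- function(i, p) -log(max(abmilPool(bags[[i]], p)$classProbs[labels[i]], 1e-12))
  for (ep in seq_len(epochs)) {
    acc <- NULL; tot <- 0
    for (i in trIdx) {
      gr <- abmilGrad(bags[[i]], params, labels[i])
      tot <- tot + gr$loss
      if (is.null(acc)) acc <- gr else
        for (nm in c("V", "U", "w", "C", "b")) acc[[nm]] <- acc[[nm]] + gr[[nm]]
    }
    n <- length(trIdx)
    for (nm in c("V", "U", "w", "C"))
      params[[nm]] <- params[[nm]] - lr * (acc[[nm]] / n + weightDecay * params[[nm]])
    params$b <- params$b - lr * acc$b / n
    trace[ep] <- tot / n
    if (length(valIdx)) {
      vl <- mean(vapply(valIdx, bagLoss, 1, p = params))
      valTrace[ep] <- vl
      if (vl < bestVal) { bestVal <- vl; best <- params; bestEpoch <- ep }
    } else {
      best <- params; bestEpoch <- ep
    }
  }
  list(params = best, lossTrace = trace, valTrace = valTrace,
       bestEpoch = bestEpoch)
}

#' Binarize a grade group into clinically significant vs not
#'
#' Clinically significant (CS) disease is grade group 2 or higher; benign
#' tissue and GG1 are not CS.
#'
#' @param ggLabel character vector of labels in BN, GG1, GG2, GG3, GG4/5.
#' @return logical vector: TRUE for CS.
#' @export
binarizeCS <- function(ggLabel) {
  if (!all(ggLabel %in% GG_LEVELS))
    stop("unknown grade-group label: ",
         paste(setdiff(ggLabel, GG_LEVELS), collapse = ", "))
  ggLabel %in% c("GG2", "GG3", "GG4/5")
}
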
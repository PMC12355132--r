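# Classification and agreement metrics.

#' Multi-class classification metrics
#'
#' One-vs-rest AUC averaged with class-support weights, support-weighted
#' precision/recall/F1 of the argmax predictions, and the confusion matrix
#' (raw counts and row-normalized).
#'
#' @param probs n x C matrix of class probabilities (columns in the order
#'   of `levels`).
#' @param labels integer (1-based) or factor true labels.
#' @param levels optional class names.
#' @return list(metrics = data.frame(auc, precision, recall, f1),
#'   perClass, confusion, confusionNorm).
#' @export
evaluateMulticlass <- function(probs, labels, levels = NULL) {
  probs <- rbind(probs)
  if (is.factor(labels)) labels <- as.integer(labels)
  n <- length(labels)
  stopifnot(nrow(probs) == n)
  C <- ncol(probs)
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: labels contain a single class")
  if (is.null(levels)) levels <- colnames(probs)
  if (is.null(levels)) levels <- paste0("class", seq_len(C))
  pred <- max.col(probs, ties.method = "first")
  support <- tabulate(labels, C)
  conf <- matrix(0L, C, C, dimnames = list(truth = levels, pred = levels))
  for (i in seq_len(n)) conf[labels[i], pred[i]] <- conf[labels[i], pred[i]] + 1L
  confNorm <- conf / pmax(rowSums(conf), 1)
  perClass <- data.frame(class = levels, support = support,
                         auc = NA_real_, precision = 0, recall = 0, f1 = 0)
  for (c in seq_len(C)) {
    tp <- conf[c, c]; fp <- sum(conf[, c]) - tp; fn <- sum(conf[c, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    perClass$precision[c] <- prec
    perClass$recall[c] <- rec
    perClass$f1[c] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    if (support[c] > 0 && support[c] < n) {
      r <- pROC::roc(response = as.integer(labels == c), predictor = probs[, c],
                     levels = c(0, 1), direction = "<", quiet = TRUE)
      perClass$auc[c] <- as.numeric(pROC::auc(r))
    }
  }
  wts <- support / sum(support)
  ok <- !is.na(perClass$auc)
  metrics <- data.frame(
    auc = sum(perClass$auc[ok] * wts[ok]) / sum(wts[ok]),
    precision = sum(perClass$precision * wts),
    recall = sum(perClass$recall * wts),
    f1 = sum(perClass$f1 * wts))
  list(metrics = metrics, perClass = perClass, confusion = conf,
       confusionNorm = confNorm)
}

#' McNemar's chi-square test for paired classifiers
#'
#' Compares two classifiers on the same cases through their discordant
#' counts: b cases only classifier A got right, c cases only B got right;
#' chi2 = (b - c)^2 / (b + c) on 1 degree of freedom (continuity
#' correction optional, off by default).
#'
#' @param correctA,correctB logical vectors: per-case correctness of the
#'   two classifiers.
#' @param correct apply the continuity correction.
#' @return list(statistic, pValue, b, c).
#' @export
mcnemarChi2 <- function(correctA, correctB, correct = FALSE) {
  stopifnot(length(correctA) == length(correctB))
  b <- sum(correctA & !correctB)
  c <- sum(!correctA & correctB)
  if (b + c == 0) stop("undefined test: no discordant pairs")
  num <- if (correct) (abs(b - c) - 1)^2 else (b - c)^2
  stat <- num / (b + c)
  list(statistic = stat, pValue = stats::pchisq(stat, 1, lower.tail = FALSE),
       b = b, c = c)
}

#' Quadratic-weighted kappa
#'
#' Chance-corrected agreement for ordinal ratings with squared-distance
#' penalty weights w_ij = (i - j)^2 / (C - 1)^2:
#' kappa = 1 - sum(w O) / sum(w E), where O is the observed contingency
#' table and E the outer product of the marginals.
#'
#' @param ratingsA,ratingsB equal-length ordinal ratings (integer or
#'   factor sharing `categories`).
#' @param categories the ordered category set; defaults to the union of
#'   observed values.
#' @return kappa in [-1, 1] (1 for identical ratings).
#' @export
quadraticWeightedKappa <- function(ratingsA, ratingsB, categories = NULL) {
  stopifnot(length(ratingsA) == length(ratingsB))
  if (length(ratingsA) == 0L) stop("empty ratings")
  if (is.null(categories)) categories <- sort(unique(c(ratingsA, ratingsB)))
  C <- length(categories)
  if (C < 2L) return(1)
  ia <- match(ratingsA, categories); ib <- match(ratingsB, categories)
  if (anyNA(ia) || anyNA(ib)) stop("ratings outside the category set")
  O <- matrix(0, C, C)
  for (k in seq_along(ia)) O[ia[k], ib[k]] <- O[ia[k], ib[k]] + 1
  O <- O / sum(O)
  E <- outer(rowSums(O), colSums(O))
  W <- outer(seq_len(C), seq_len(C), function(i, j) (i - j)^2) / (C - 1)^2
  1 - sum(W * O) / sum(W * E)
}
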
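## Subject- and limb-specific random-forest models with stratified k-fold
## cross-validation; every unambiguous block is predicted exactly once by a
## model that never saw it.

#' Confusion-matrix metrics with functional as the positive class
#'
#' Accuracy is the ratio of correct classifications to total cases;
#' sensitivity the ratio of true positives to all positive cases;
#' specificity the ratio of true negatives to all negative cases.
#'
#' @param predictions,truths equal-length character vectors over
#'   `functional/nonfunctional`.
#' @param positive positive class (default `"functional"`).
#' @return list with `confusion` (named TP/FP/TN/FN), `accuracy`,
#'   `sensitivity`, `specificity`. A metric whose denominator is empty is
#'   `NA` with a warning.
#' @export
confusionMetrics <- function(predictions, truths, positive = .LBL_FUN) {
  if (length(predictions) != length(truths)) stopf("length mismatch")
  pos <- truths == positive
  tp <- sum(pos & predictions == positive)
  fn <- sum(pos & predictions != positive)
  tn <- sum(!pos & predictions != positive)
  fp <- sum(!pos & predictions == positive)
  sens <- if (tp + fn == 0) { warning("no positive cases: sensitivity undefined"); NA_real_ } else tp / (tp + fn)
  spec <- if (tn + fp == 0) { warning("no negative cases: specificity undefined"); NA_real_ } else tn / (tn + fp)
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       accuracy = (tp + tn) / length(truths),
       sensitivity = sens, specificity = spec)
}

## stratified fold assignment: within each class, seeded shuffle then
## round-robin deal, so per-fold class proportions differ from the global
## proportion by at most one block
stratifiedFolds <- function(labels, k, seed) {
  fold <- rep(NA_integer_, length(labels))
  withSeed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated subject/limb model
#'
#' Trains one random forest per fold on the unambiguous blocks of the other
#' folds and predicts the held-out fold, so each unambiguous block is
#' predicted exactly once by a model not trained on it. Ambiguous blocks are
#' never trained on; each fold's model predicts them and the per-block
#' majority across folds is their resolved label (used for use-ratio
#' estimation, never for the confusion metrics). Fully seeded.
#'
#' @param blockSet a [LabeledBlockSet-class].
#' @param config a [ModelConfig-class].
#' @return a [SubjectModelResult-class].
#' @export
crossvalSubject <- function(blockSet, config = ModelConfig()) {
  validObject(config)
  feats <- blockSet@features
  labs <- blockSet@blockLabels
  k <- as.integer(config@cvFolds)
  elig <- labs %in% c(.LBL_FUN, .LBL_NON)
  for (cls in c(.LBL_FUN, .LBL_NON)) {
    if (sum(labs == cls) < k)
      stopf("insufficient class support: %d '%s' blocks for %d folds",
            sum(labs == cls), cls, k)
  }
  y <- factor(labs[elig], levels = c(.LBL_FUN, .LBL_NON))
  xe <- feats[elig, , drop = FALSE]
  xa <- feats[!elig, , drop = FALSE]
  fold <- stratifiedFolds(labs[elig], k,
                          deriveSeed(config@shuffleSeed, "folds", blockSet@limb))
  mtry <- if (is.na(config@mtry)) floor(sqrt(ncol(feats))) else config@mtry

  predElig <- rep(NA_character_, sum(elig))
  predAmbVotes <- matrix(NA_character_, nrow(xa), k)
  for (f in seq_len(k)) {
    tr <- fold != f
    rf <- withSeed(deriveSeed(config@shuffleSeed, "rf", blockSet@limb, f),
      randomForest::randomForest(
        x = xe[tr, , drop = FALSE], y = y[tr],
        ntree = config@nTrees, mtry = mtry, nodesize = config@minLeaf))
    predElig[fold == f] <-
      as.character(stats::predict(rf, xe[fold == f, , drop = FALSE]))
    if (nrow(xa))
      predAmbVotes[, f] <- as.character(stats::predict(rf, xa))
  }
  predAmb <- if (nrow(xa)) apply(predAmbVotes, 1, function(v)
    names(which.max(table(factor(v, c(.LBL_FUN, .LBL_NON)))))) else character(0)

  predictions <- rep(NA_character_, length(labs))
  predictions[elig] <- predElig
  predictions[!elig] <- predAmb
  folds <- rep(NA_real_, length(labs))
  folds[elig] <- fold

  m <- confusionMetrics(predElig, as.character(y))
  new("SubjectModelResult", limb = blockSet@limb, predictions = predictions,
      folds = folds, confusion = m$confusion, accuracy = m$accuracy,
      sensitivity = m$sensitivity, specificity = m$specificity)
}
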
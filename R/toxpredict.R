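# Species-specific antibacterial-activity classification from molecular
# features: stratified repeated splits, random-forest probabilities,
# prevalence thresholding and imbalance-aware metrics.

#' Select species with enough hits to model
#'
#' Keeps species whose hit counts in both datasets are strictly greater
#' than \code{min_hits}.
#'
#' @param hit_counts data.frame with columns \code{species}, \code{n_hits_A},
#'   \code{n_hits_B}.
#' @param min_hits strict threshold, default 20.
#' @return character vector of species ids.
#' @export
selectSpecies <- function(hit_counts, min_hits = 20L) {
  sel <- hit_counts$n_hits_A > min_hits & hit_counts$n_hits_B > min_hits
  hit_counts$species[sel]
}

#' Repeated stratified train/test splits
#'
#' Generates \code{n_splits} independent stratified shuffle-splits: each
#' split holds out \code{test_fraction} of every class (rounded per class),
#' so hit frequencies match between train and test. Deterministic under
#' \code{seed}.
#'
#' @param labels binary (0/1) label vector.
#' @param test_fraction held-out fraction, default 0.2.
#' @param n_splits number of splits, default 20.
#' @param seed integer seed.
#' @return list of \code{n_splits} lists with integer \code{train} and
#'   \code{test} index vectors (a disjoint, exhaustive partition).
#' @export
stratifiedSplits <- function(labels, test_fraction = 0.2, n_splits = 20L,
                             seed = 1L) {
  .stopIfNot(all(labels %in% c(0, 1)), "labels must be binary")
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  .stopIfNot(length(pos) >= 2L && length(neg) >= 2L,
             "each class needs >= 2 members")
  set.seed(seed)
  n_pos_test <- round(test_fraction * length(pos))
  n_neg_test <- round(test_fraction * length(neg))
  lapply(seq_len(n_splits), function(i) {
    test <- sort(c(sample(pos, n_pos_test), sample(neg, n_neg_test)))
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

#' Random-forest class probabilities
#'
#' Fits a probability random forest (500 trees, square-root feature
#' sampling, unlimited depth) on the training slice and returns the
#' positive-class probability for each test compound. Deterministic under
#' \code{seed}. Single-class training sets are rejected.
#'
#' @param train_x,train_y training features (matrix) and binary labels.
#' @param test_x test feature matrix (same columns).
#' @param n_trees number of trees, default 500.
#' @param seed integer seed.
#' @return numeric vector of positive-class probabilities.
#' @export
fitPredictRf <- function(train_x, train_y, test_x, n_trees = 500L, seed = 1L) {
  .stopIfNot(ncol(train_x) == ncol(test_x),
             "train and test feature counts differ")
  .stopIfNot(length(unique(train_y)) == 2L,
             "training set must contain both classes")
  if (is.null(colnames(train_x))) {
    colnames(train_x) <- colnames(test_x) <- paste0("f", seq_len(ncol(train_x)))
  }
  y <- factor(train_y, levels = c(0, 1))
  fit <- ranger::ranger(x = train_x, y = y, num.trees = n_trees,
                        mtry = floor(sqrt(ncol(train_x))),
                        min.node.size = 1L,  # grow to purity (unlimited depth)
                        probability = TRUE, seed = seed, num.threads = 1L)
  predict(fit, data = test_x, num.threads = 1L)$predictions[, "1"]
}

#' Threshold probabilities at the training prevalence
#'
#' Classifies a compound as active when its predicted probability is at
#' least the hit frequency of the training set -- the operating point suited
#' to imbalanced screens, where the default 0.5 cutoff would call almost
#' nothing active.
#'
#' @param probabilities predicted positive-class probabilities.
#' @param train_hit_frequency training-set positive fraction in [0, 1].
#' @return integer 0/1 predictions.
#' @export
thresholdAtPrevalence <- function(probabilities, train_hit_frequency) {
  .stopIfNot(train_hit_frequency >= 0 && train_hit_frequency <= 1,
             "train_hit_frequency must lie in [0, 1]")
  as.integer(probabilities >= train_hit_frequency)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; chance level 0.5 regardless of
#' class imbalance. Undefined (NA with a warning) when a class is absent
#' from the truth.
#'
#' @param truth binary truth vector.
#' @param predictions binary predictions.
#' @return balanced accuracy in [0, 1].
#' @examples
#' balancedAccuracy(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 0.75
#' @export
balancedAccuracy <- function(truth, predictions) {
  tp <- sum(truth == 1 & predictions == 1)
  fn <- sum(truth == 1 & predictions == 0)
  tn <- sum(truth == 0 & predictions == 0)
  fp <- sum(truth == 0 & predictions == 1)
  if (tp + fn == 0L || tn + fp == 0L) {
    warning("a class is absent from truth; balanced accuracy undefined")
    return(NA_real_)
  }
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise PR area \code{AP = sum_k (R_k - R_(k-1)) P_k} over the list
#' ranked by decreasing score; tied scores are processed as one block.
#' Undefined (NA with a warning) without positives.
#'
#' @param truth binary truth vector.
#' @param scores predicted scores or probabilities.
#' @return average precision in [0, 1].
#' @export
averagePrecision <- function(truth, scores) {
  n_pos <- sum(truth == 1)
  if (n_pos == 0L) {
    warning("no positives in truth; average precision undefined")
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  truth <- truth[o]
  scores <- scores[o]
  # block boundaries at distinct scores
  ends <- cumsum(rle(scores)$lengths)
  tp_cum <- cumsum(truth == 1)[ends]
  n_cum <- ends
  recall <- tp_cum / n_pos
  precision <- tp_cum / n_cum
  sum(diff(c(0, recall)) * precision)
}

#' Cross-validated species model
#'
#' Runs the full pipeline for one species: repeated stratified 8:2 splits,
#' a probability random forest per split, thresholding at the split's
#' training hit frequency, and imbalance-aware metrics per split.
#'
#' @param dataset a \linkS4class{ToxDataset}.
#' @param species label column to model.
#' @param n_splits number of stratified splits, default 20.
#' @param n_trees forest size, default 500.
#' @param seed integer seed.
#' @return data.frame with one row per split: \code{balanced_accuracy},
#'   \code{average_precision}, \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @export
crossValidateSpecies <- function(dataset, species, n_splits = 20L,
                                 n_trees = 500L, seed = 1L) {
  x <- toxFeatures(dataset)
  y <- toxLabels(dataset)[, species]
  splits <- stratifiedSplits(y, n_splits = n_splits, seed = seed)
  res <- lapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    prob <- fitPredictRf(x[sp$train, , drop = FALSE], y[sp$train],
                         x[sp$test, , drop = FALSE], n_trees = n_trees,
                         seed = seed + i)
    pred <- thresholdAtPrevalence(prob, mean(y[sp$train]))
    truth <- y[sp$test]
    data.frame(split_id = i,
               balanced_accuracy = balancedAccuracy(truth, pred),
               average_precision = averagePrecision(truth, prob),
               TP = sum(truth == 1 & pred == 1),
               FP = sum(truth == 0 & pred == 1),
               TN = sum(truth == 0 & pred == 0),
               FN = sum(truth == 1 & pred == 0))
  })
  do.call(rbind, res)
}

#' Shuffled-label null distribution
#'
#' Re-runs the full cross-validation pipeline on label-permuted copies of
#' the dataset, yielding the chance-level distribution of both metrics
#' against which real performance is judged.
#'
#' @param dataset a \linkS4class{ToxDataset}.
#' @param species label column to model.
#' @param n_shuffles number of label permutations, default 20.
#' @param n_splits splits per shuffle, default 20.
#' @param n_trees forest size, default 500.
#' @param seed integer seed.
#' @return data.frame with one row per shuffle: mean
#'   \code{balanced_accuracy} and \code{average_precision} across splits.
#' @export
shuffledLabelNull <- function(dataset, species, n_shuffles = 20L,
                              n_splits = 20L, n_trees = 500L, seed = 1L) {
  x <- toxFeatures(dataset)
  y <- toxLabels(dataset)[, species]
  res <- lapply(seq_len(n_shuffles), function(s) {
    set.seed(seed + 1000L * s)
    ys <- sample(y)
    ds <- ToxDataset(x, matrix(ys, ncol = 1L,
                               dimnames = list(rownames(x), species)))
    cv <- crossValidateSpecies(ds, species, n_splits = n_splits,
                               n_trees = n_trees, seed = seed + s)
    data.frame(shuffle = s,
               balanced_accuracy = mean(cv$balanced_accuracy, na.rm = TRUE),
               average_precision = mean(cv$average_precision, na.rm = TRUE))
  })
  do.call(rbind, res)
}
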
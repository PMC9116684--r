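#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn Nonnegative integer counts with positive sum.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  if (sum(counts) == 0) stop("all-zero confusion counts")
  (tp + tn) / sum(counts)
}

#' F1 score from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`; 0 when `TP = 0` with errors present, and
#' (with a warning) 1 when there are no positives anywhere.
#'
#' @param tp,fp,fn Nonnegative integer counts.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(tp, fp, fn) {
  counts <- c(tp, fp, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  if (tp == 0 && fp == 0 && fn == 0) {
    warning("no positives anywhere; F1 defined as 1")
    return(1)
  }
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

confusion_counts <- function(truth, pred) {
  c(tp = sum(truth == 1L & pred == 1L),
    tn = sum(truth == 0L & pred == 0L),
    fp = sum(truth == 0L & pred == 1L),
    fn = sum(truth == 1L & pred == 0L))
}

# Stratified fold assignment: within each class, a seeded permutation is
# dealt cyclically over folds, so per-fold class proportions differ from
# the global ones by less than one sample.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' Per iteration a fresh stratified fold assignment is drawn (seeded by
#' `base_seed + iteration`); the per-iteration accuracy is the average of
#' the k validation-fold accuracies, and F1 (positive class: sensitive) is
#' computed on the pooled out-of-fold predictions of that iteration.
#'
#' @param features A `feature_matrix`.
#' @param config A [classifier_config()].
#' @param k Folds (lowered with a warning if a class has fewer members).
#' @param n_iterations Number of repeats.
#' @param base_seed Seed base for the fold assignments.
#' @return A `cv_result`: `fold_acc` (iterations x k matrix), `mean_acc`
#'   and `f1` (per-iteration vectors), `k`, `n_iterations`, `seeds`.
#' @export
repeated_stratified_cv <- function(features, config, k = 10L,
                                   n_iterations = 50L, base_seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  y <- features$y
  min_class <- min(sum(y == 1L), sum(y == 0L))
  if (min_class < 2L) stop("need at least 2 samples per class")
  if (min_class < k) {
    warning("k lowered from ", k, " to ", min_class,
            " (smallest class size)")
    k <- min_class
  }
  seeds <- base_seed + seq_len(n_iterations)
  fold_acc <- matrix(NA_real_, n_iterations, k)
  f1 <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    folds <- withr::with_seed(seeds[it], stratified_folds(y, k))
    pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (f in seq_len(k)) {
      tr <- which(folds != f); va <- which(folds == f)
      model <- train_classifier(subset_features(features, tr), config)
      pred <- predict(model, features$x[va, , drop = FALSE])
      cc <- confusion_counts(y[va], pred)
      fold_acc[it, f] <- accuracy(cc["tp"], cc["tn"], cc["fp"], cc["fn"])
      pooled <- pooled + cc
    }
    f1[it] <- f1_score(pooled["tp"], pooled["fp"], pooled["fn"])
  }
  structure(list(fold_acc = fold_acc, mean_acc = rowMeans(fold_acc),
                 f1 = f1, k = k, n_iterations = n_iterations,
                 seeds = seeds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d x %d-fold CV; mean accuracy %.3f (sd %.3f), mean F1 %.3f\n",
              x$n_iterations, x$k, mean(x$mean_acc), sd(x$mean_acc),
              mean(x$f1)))
  invisible(x)
}
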
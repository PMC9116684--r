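#' Remove one edge's feature column
#'
#' @param features A `feature_matrix`.
#' @param target,regulator Edge whose column is removed.
#' @return The `feature_matrix` without that column (column map renumbered).
#' @export
ablate_feature <- function(features, target, regulator) {
  stopifnot(inherits(features, "feature_matrix"))
  cm <- features$column_map
  hit <- which(cm$target == target & cm$regulator == regulator)
  if (length(hit) != 1L)
    stop("edge not in the column map: ", target, " <- ", regulator)
  out <- features
  out$x <- features$x[, -hit, drop = FALSE]
  out$column_map <- cm[-hit, , drop = FALSE]
  out$column_map$column <- seq_len(nrow(out$column_map))
  rownames(out$column_map) <- NULL
  out
}

#' Pooled two-sample t-test on accuracy distributions
#'
#' Equal-variance two-sample t statistic with pooled standard deviation
#' `sp = sqrt(((N1-1) s1^2 + (N2-1) s2^2) / (N1 + N2 - 2))` and a
#' two-sided p-value from Student's t with `N1 + N2 - 2` degrees of
#' freedom. Degenerate inputs: zero pooled variance with equal means gives
#' `T = 0, p = 1`; with unequal means, `p = 0` with a warning.
#'
#' @param acc_full,acc_ablated Numeric samples (each of size >= 2).
#' @return List with `t`, `p_value`, `df`, the two means and SDs.
#' @export
pooled_t_test <- function(acc_full, acc_ablated) {
  n1 <- length(acc_full); n2 <- length(acc_ablated)
  if (n1 < 2L || n2 < 2L) stop("both samples must have size >= 2")
  m1 <- mean(acc_full); m2 <- mean(acc_ablated)
  s1 <- sd(acc_full); s2 <- sd(acc_ablated)
  df <- n1 + n2 - 2L
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  if (se == 0) {
    if (m1 == m2) {
      t_stat <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means; p-value set to 0")
      t_stat <- sign(m1 - m2) * Inf; p <- 0
    }
  } else {
    t_stat <- (m1 - m2) / se
    p <- 2 * pt(-abs(t_stat), df)
  }
  list(t = t_stat, p_value = p, df = df, mean_full = m1, mean_ablated = m2,
       sd_full = s1, sd_ablated = s2)
}

#' Sign of an edge's contribution to prediction accuracy
#'
#' `"+"` when the full model is more accurate than the ablated one (the
#' edge helps), `"-"` otherwise; an exact tie is reported as `"-"` with a
#' warning.
#'
#' @param mean_full,mean_ablated Mean accuracies with and without the edge.
#' @return `"+"` or `"-"`.
#' @export
pn_sign <- function(mean_full, mean_ablated) {
  stopifnot(is.finite(mean_full), is.finite(mean_ablated))
  if (mean_full == mean_ablated) {
    warning("exact tie in mean accuracy; PN sign reported as '-'")
    return("-")
  }
  if (mean_full > mean_ablated) "+" else "-"
}

#' Edge importance by ablation (explainable prediction)
#'
#' The full model's repeated-CV accuracy distribution is compared, edge by
#' edge, with the distribution obtained after deleting that edge's feature
#' column and re-running repeated CV with fresh fold seeds; the shift is
#' tested with [pooled_t_test()] and edges with p below `alpha` form the
#' crucial set.
#'
#' @param features A `feature_matrix`.
#' @param config A [classifier_config()].
#' @param k CV folds.
#' @param n_it Repeats for the full model.
#' @param n_it_ablated Repeats per ablated model (default `n_it`).
#' @param candidate_edges Data frame with columns `target`, `regulator`;
#'   default: every edge whose feature column is nonzero in at least one
#'   sample.
#' @param alpha Crucial-edge p-value threshold.
#' @param base_seed Seed base for the CV fold assignments.
#' @param paired_folds If `TRUE` (default) every ablated run reuses the
#'   full-model run's fold assignments, making the comparison a matched
#'   one: deleting a feature the classifier provably ignores (e.g. an
#'   all-zero column) then yields identical accuracy vectors and p = 1,
#'   and the pooled (unpaired) test is conservative under the induced
#'   positive correlation. `FALSE` draws fresh, independent fold seeds per
#'   ablated run, in which case an irrelevant feature's p-value is uniform
#'   rather than near 1.
#' @param p_adjust `"none"` (default: raw p-values are thresholded) or
#'   `"BH"` (Benjamini-Hochberg before thresholding).
#' @return List with `importance` (data frame sorted by p-value, ties by
#'   target then regulator: target, regulator, mean/sd accuracies, sizes,
#'   `t`, `p_value`, `pn`), `crucial` (a `crucial_edges` object) and the
#'   full-model `cv_result`.
#' @export
run_xprediction <- function(features, config, k = 10L, n_it = 50L,
                            n_it_ablated = n_it, candidate_edges = NULL,
                            alpha = 0.01, base_seed = 1L,
                            paired_folds = TRUE,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(features, "feature_matrix"))
  if (is.null(candidate_edges)) {
    nz <- colSums(features$x != 0) > 0
    candidate_edges <- features$column_map[nz, c("target", "regulator"),
                                           drop = FALSE]
  }
  if (nrow(candidate_edges) == 0L) stop("empty candidate edge set")
  key_cm <- paste(features$column_map$target, features$column_map$regulator)
  key_ce <- paste(candidate_edges$target, candidate_edges$regulator)
  if (!all(key_ce %in% key_cm))
    stop("candidate edge(s) not in the column map")

  cv_full <- repeated_stratified_cv(features, config, k, n_it, base_seed)

  rows <- vector("list", nrow(candidate_edges))
  for (i in seq_len(nrow(candidate_edges))) {
    tgt <- candidate_edges$target[i]; reg <- candidate_edges$regulator[i]
    abl <- ablate_feature(features, tgt, reg)
    seed_i <- if (paired_folds) base_seed
              else base_seed + 7919L * i # fresh, per-edge fold seeds
    cv_abl <- repeated_stratified_cv(abl, config, k, n_it_ablated, seed_i)
    tt <- pooled_t_test(cv_full$mean_acc, cv_abl$mean_acc)
    pn <- withCallingHandlers(pn_sign(tt$mean_full, tt$mean_ablated),
                              warning = function(w) invokeRestart("muffleWarning"))
    rows[[i]] <- data.frame(
      target = tgt, regulator = reg,
      mean_acc_full = tt$mean_full, mean_acc_ablated = tt$mean_ablated,
      sd_full = tt$sd_full, sd_ablated = tt$sd_ablated,
      n_full = n_it, n_ablated = n_it_ablated,
      t = tt$t, p_value = tt$p_value, pn = pn,
      stringsAsFactors = FALSE)
  }
  importance <- do.call(rbind, rows)
  if (p_adjust == "BH")
    importance$p_value <- stats::p.adjust(importance$p_value, "BH")
  importance <- importance[order(importance$p_value, importance$target,
                                 importance$regulator), , drop = FALSE]
  rownames(importance) <- NULL
  crucial <- structure(
    list(edges = importance[importance$p_value < alpha, , drop = FALSE],
         alpha = alpha,
         modulator_drug = features$modulator_drug,
         response_drug = features$response_drug),
    class = "crucial_edges")
  list(importance = importance, crucial = crucial, cv_full = cv_full)
}

#' @export
print.crucial_edges <- function(x, ...) {
  cat("crucial_edges:", nrow(x$edges), "edges with p <", x$alpha,
      sprintf("(%s networks -> %s response)\n",
              x$modulator_drug %||% "?", x$response_drug %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
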
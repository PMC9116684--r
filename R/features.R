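#' Select target genes by dependency-sensitivity correlation
#'
#' Per gene, the Pearson correlation between its dependency-screen row and
#' the drug's sensitivity over shared samples; genes are ranked by absolute
#' correlation (a strongly negative dependency-sensitivity correlation is
#' as informative as a positive one) and the top `ceil(top_fraction * G)`
#' returned. Zero-variance rows get correlation 0 with a warning; ties are
#' broken by gene id.
#'
#' @param dep Genes x samples dependency matrix.
#' @param sens Samples x drugs sensitivity matrix.
#' @param drug Drug id.
#' @param top_fraction Fraction of genes to keep (default 0.01, the "top
#'   1%" convention).
#' @param signed Rank by signed correlation (descending) instead of
#'   absolute value.
#' @return Character vector of selected gene ids, in rank order, with the
#'   per-gene correlations as attribute `"correlation"`.
#' @export
dependency_correlation_filter <- function(dep, sens, drug,
                                          top_fraction = 0.01,
                                          signed = FALSE) {
  stopifnot(is.matrix(dep), is.matrix(sens))
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  if (!drug %in% colnames(sens)) stop("unknown drug id: ", drug)
  samples <- intersect(colnames(dep), rownames(sens))
  if (length(samples) < 3L) stop("need at least 3 shared samples")
  ds <- sens[samples, drug]
  D <- dep[, samples, drop = FALSE]
  vr <- apply(D, 1L, var)
  r <- numeric(nrow(D))
  ok <- vr > 0
  if (any(!ok))
    warning(sum(!ok), " zero-variance dependency row(s); correlation set to 0")
  if (any(ok)) r[ok] <- as.numeric(cor(t(D[ok, , drop = FALSE]), ds))
  names(r) <- rownames(D)
  score <- if (signed) r else abs(r)
  ord <- order(-score, names(r))
  k <- ceiling(top_fraction * nrow(D))
  sel <- names(r)[ord][seq_len(k)]
  attr(sel, "correlation") <- r[sel]
  sel
}

#' Compute the regulatory-effect tensor
#'
#' Regulatory effect of edge (l, j) in sample alpha: the fitted coefficient
#' times the regulator's expression in that sample. By default the
#' regulator expression is z-scored per gene across the stack's samples
#' (consistent with the scale-free fitted coefficients); `scale = "raw"`
#' uses expression as given.
#'
#' @param stack A `network_stack`.
#' @param expr Genes x samples expression matrix covering the stack's
#'   regulators and samples.
#' @param scale `"standardized"` (default) or `"raw"` regulator expression.
#' @return A `re_tensor`: `values` (n x L x J array), axis ids,
#'   `modulator_drug`.
#' @export
compute_regulatory_effects <- function(stack, expr,
                                       scale = c("standardized", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(stack, "network_stack"), is.matrix(expr))
  missing_g <- setdiff(stack$regulator_ids, rownames(expr))
  if (length(missing_g))
    stop("regulator(s) absent from expression matrix: ",
         paste(head(missing_g, 5L), collapse = ", "))
  missing_s <- setdiff(stack$sample_ids, colnames(expr))
  if (length(missing_s))
    stop("sample(s) absent from expression matrix: ",
         paste(head(missing_s, 5L), collapse = ", "))
  X <- t(expr[stack$regulator_ids, stack$sample_ids, drop = FALSE])
  if (scale == "standardized") {
    X <- base::scale(X)
    X[is.nan(X)] <- 0 # constant regulator: zero signal either way
  }
  values <- stack$coefficients
  d <- dim(values)
  for (l in seq_len(d[2L])) {
    bl <- values[, l, , drop = FALSE]
    dim(bl) <- c(d[1L], d[3L])
    values[, l, ] <- bl * X
  }
  structure(list(values = values, sample_ids = stack$sample_ids,
                 target_ids = stack$target_ids,
                 regulator_ids = stack$regulator_ids,
                 modulator_drug = stack$modulator_drug),
            class = "re_tensor")
}

#' @export
print.re_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("re_tensor:", d[1L], "samples x", d[2L], "targets x", d[3L],
      "regulators (modulator drug:", x$modulator_drug, ")\n")
  invisible(x)
}

#' Label samples as drug sensitive / resistant / intermediate
#'
#' Sensitive: sensitivity strictly below the `p_low`th empirical
#' percentile; resistant: strictly above the `p_high`th. Percentiles use
#' linear interpolation between order statistics (R's default type-7
#' quantile), which is documented because the cut values depend on the
#' convention.
#'
#' @param sens Samples x drugs sensitivity matrix.
#' @param drug Drug id providing the response.
#' @param p_low,p_high Percentiles (defaults 10 and 90).
#' @return A `sensitivity_labels` object: `labels` (named character),
#'   `p_low_value`, `p_high_value`, `response_drug`, class counts.
#' @export
label_sensitivity <- function(sens, drug, p_low = 10, p_high = 90) {
  stopifnot(is.matrix(sens))
  if (!drug %in% colnames(sens)) stop("unknown drug id: ", drug)
  ds <- sens[, drug]
  if (length(ds) < 10L) stop("need at least 10 samples to set percentiles")
  lo <- as.numeric(quantile(ds, p_low / 100, type = 7))
  hi <- as.numeric(quantile(ds, p_high / 100, type = 7))
  labels <- ifelse(ds < lo, "sensitive",
                   ifelse(ds > hi, "resistant", "intermediate"))
  names(labels) <- rownames(sens)
  counts <- c(sensitive = sum(labels == "sensitive"),
              resistant = sum(labels == "resistant"),
              intermediate = sum(labels == "intermediate"))
  message("labels for ", drug, ": ", counts[["sensitive"]], " sensitive, ",
          counts[["resistant"]], " resistant, ",
          counts[["intermediate"]], " intermediate")
  structure(list(labels = labels, p_low_value = lo, p_high_value = hi,
                 p_low = p_low, p_high = p_high,
                 response_drug = drug, counts = counts),
            class = "sensitivity_labels")
}

#' Flatten regulatory effects into a classification feature matrix
#'
#' Intermediate samples are dropped; each retained sample's L x J
#' regulatory-effect matrix is flattened row-major (target-major, regulator
#' fastest) into one feature row. Labels are binary: sensitive = 1,
#' resistant = 0.
#'
#' @param tensor A `re_tensor`.
#' @param labels A `sensitivity_labels` object covering the tensor's
#'   samples.
#' @return A `feature_matrix`: `x` (samples x L*J), `y` (named 0/1
#'   integer), `column_map` (data frame column/target/regulator),
#'   `modulator_drug`, `response_drug`.
#' @export
build_feature_matrix <- function(tensor, labels) {
  stopifnot(inherits(tensor, "re_tensor"),
            inherits(labels, "sensitivity_labels"))
  lab <- labels$labels[tensor$sample_ids]
  if (anyNA(lab)) stop("labels missing for some tensor samples")
  keep <- which(lab != "intermediate")
  if (sum(lab == "sensitive") < 2L || sum(lab == "resistant") < 2L)
    stop("need at least 2 samples in each of the sensitive/resistant classes")
  L <- length(tensor$target_ids); J <- length(tensor$regulator_ids)
  column_map <- data.frame(
    column = seq_len(L * J),
    target = rep(tensor$target_ids, each = J),
    regulator = rep(tensor$regulator_ids, times = L),
    stringsAsFactors = FALSE)
  x <- t(vapply(keep, function(a) {
    ra <- tensor$values[a, , , drop = FALSE]
    dim(ra) <- c(L, J)
    as.vector(t(ra)) # row-major: target-major, regulator fastest
  }, numeric(L * J)))
  rownames(x) <- tensor$sample_ids[keep]
  colnames(x) <- paste(column_map$target, column_map$regulator, sep = "|")
  y <- stats::setNames(as.integer(lab[keep] == "sensitive"), rownames(x))
  structure(list(x = x, y = y, column_map = column_map,
                 modulator_drug = tensor$modulator_drug,
                 response_drug = labels$response_drug),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$x), "samples x", ncol(x$x), "edge features",
      sprintf("(%d sensitive / %d resistant)\n", sum(x$y == 1L),
              sum(x$y == 0L)))
  invisible(x)
}

#' Restrict a feature matrix to a subset of its samples
#' @param features A `feature_matrix`.
#' @param samples Sample ids or indices to keep.
#' @return A `feature_matrix` on the subset.
#' @export
subset_features <- function(features, samples) {
  out <- features
  out$x <- features$x[samples, , drop = FALSE]
  out$y <- features$y[samples]
  out
}
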
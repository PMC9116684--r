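#' Gaussian modulator kernel
#'
#' `exp(-(m_i - m_alpha)^2 / b)`: the weight sample i receives when fitting
#' the local network anchored at modulator value `m_alpha` with bandwidth
#' `b`. Symmetric in its first two arguments; equals 1 at zero distance and
#' increases to 1 as `b` grows.
#'
#' @param m_i,m_alpha Modulator values (vectorized).
#' @param b Positive bandwidth.
#' @return Kernel weight(s) in (0, 1].
#' @export
gaussian_kernel <- function(m_i, m_alpha, b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("bandwidth b must be a positive number")
  exp(-(m_i - m_alpha)^2 / b)
}

#' Kernel weights anchored at one sample
#'
#' @param modulator Named per-sample modulator values.
#' @param anchor Sample id (or index) of the anchor.
#' @param bandwidth Positive bandwidth.
#' @return A `kernel_weights` object: weights, anchor id, bandwidth.
#' @export
kernel_weights <- function(modulator, anchor, bandwidth) {
  if (is.character(anchor)) {
    if (!anchor %in% names(modulator)) stop("unknown anchor sample: ", anchor)
    m_a <- modulator[[anchor]]
  } else {
    m_a <- modulator[[anchor]]
    anchor <- if (is.null(names(modulator))) as.character(anchor)
              else names(modulator)[anchor]
  }
  w <- gaussian_kernel(modulator, m_a, bandwidth)
  structure(list(weights = w, anchor = anchor, bandwidth = bandwidth),
            class = "kernel_weights")
}

#' Penalty configuration for the weighted elastic net
#'
#' @param lambda Fixed penalty strength, or `NULL` to select by
#'   kernel-weighted K-fold cross-validation over a log-spaced grid.
#' @param mixing Elastic-net L1 fraction in \[0, 1\] (1 = lasso).
#' @param nlambda Grid size for CV selection.
#' @param lambda_min_ratio Smallest grid value relative to `lambda_max`
#'   (the smallest lambda with an all-zero solution).
#' @param nfolds Folds for CV selection.
#' @param rule `"1se"` (default; sparsest lambda within one standard error
#'   of the CV minimum) or `"min"`.
#' @return A `penalty_config` list.
#' @export
penalty_config <- function(lambda = NULL, mixing = 0.5, nlambda = 50L,
                           lambda_min_ratio = 1e-3, nfolds = 5L,
                           rule = c("1se", "min")) {
  rule <- match.arg(rule)
  if (!is.null(lambda) && (lambda < 0 || !is.finite(lambda)))
    stop("lambda must be nonnegative")
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0, 1]")
  structure(list(lambda = lambda, mixing = mixing,
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 nfolds = as.integer(nfolds), rule = rule),
            class = "penalty_config")
}

#' Fit a weighted elastic net by coordinate descent
#'
#' Minimises
#' `1/2 * sum_i w_i (y_i - x_i' beta)^2 +
#'  lambda * (mixing * sum|beta_j| + (1 - mixing)/2 * sum beta_j^2)`
#' exactly as written (no intercept, no internal standardisation, weights
#' used as given). Converged when the largest coefficient change in a
#' sweep falls below `tol`.
#'
#' @param X n x p predictor matrix.
#' @param y Length-n response.
#' @param w Kernel weights: a `kernel_weights` object or a nonnegative
#'   numeric vector with positive sum.
#' @param lambda Nonnegative penalty strength.
#' @param mixing L1 fraction in \[0, 1\].
#' @param beta0 Optional warm start.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Sweep limit; non-convergence is an error.
#' @param trace Record the objective after every sweep (returned as the
#'   `"objective_trace"` attribute; it is non-increasing).
#' @return Coefficient vector (named after `colnames(X)`).
#' @export
fit_weighted_elastic_net <- function(X, y, w, lambda, mixing = 0.5,
                                     beta0 = NULL, tol = 1e-6,
                                     max_iter = 10000L, trace = FALSE) {
  if (inherits(w, "kernel_weights")) w <- w$weights
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) == length(w))
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be nonnegative with positive sum")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (is.null(beta0)) beta0 <- numeric(ncol(X))
  fit <- .elnet_fit_cpp(X, as.numeric(y), as.numeric(w), lambda, mixing,
                        as.numeric(beta0), tol, as.integer(max_iter), trace)
  if (!fit$converged)
    stop("coordinate descent did not converge in ", max_iter,
         " sweeps (lambda = ", signif(lambda, 3), ")")
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(X)
  if (trace) attr(beta, "objective_trace") <- fit$objective_trace
  beta
}

#' Objective value of the weighted elastic net
#' @inheritParams fit_weighted_elastic_net
#' @param beta Coefficient vector.
#' @return The penalised objective (a scalar).
#' @export
weighted_elastic_net_objective <- function(X, y, w, beta, lambda,
                                           mixing = 0.5) {
  if (inherits(w, "kernel_weights")) w <- w$weights
  .elnet_objective_cpp(as.matrix(X), as.numeric(y), as.numeric(w),
                       as.numeric(beta), lambda, mixing)
}

# Smallest lambda with an all-zero solution: max_j |x_j' (w * y)| / mixing.
lambda_max_value <- function(X, y, w, mixing) {
  mx <- max(abs(crossprod(X, w * y)))
  if (mixing <= 0) return(mx * 1e3) # pure ridge never hits exact zero
  mx / mixing
}

lambda_grid <- function(X, y, w, penalty) {
  lmax <- lambda_max_value(X, y, w, penalty$mixing)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * penalty$lambda_min_ratio),
          length.out = penalty$nlambda))
}

# Deterministic folds for kernel-weighted CV: samples ordered by kernel
# distance from the anchor, folds assigned cyclically, so every fold spans
# the weight range and repeated runs are bit-identical without RNG.
kernel_cv_folds <- function(w, nfolds) {
  ord <- order(-w, seq_along(w))
  folds <- integer(length(w))
  folds[ord] <- rep_len(seq_len(nfolds), length(w))
  folds
}

# Kernel-weighted K-fold CV over a lambda path; returns the selected lambda
# and the full path diagnostics.
cv_lambda <- function(X, y, w, penalty, tol = 1e-6, max_iter = 10000L) {
  grid <- lambda_grid(X, y, w, penalty)
  nfolds <- min(penalty$nfolds, nrow(X))
  folds <- kernel_cv_folds(w, nfolds)
  err <- matrix(NA_real_, nfolds, length(grid))
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    if (sum(w[tr]) <= 0 || sum(tr) < 2L) next
    path <- .elnet_path_cpp(X[tr, , drop = FALSE], y[tr], w[tr], grid,
                            penalty$mixing, tol, as.integer(max_iter))
    pred <- X[!tr, , drop = FALSE] %*% path$coefficients
    wv <- w[!tr]
    err[f, ] <- colSums(wv * (y[!tr] - pred)^2) / sum(wv)
  }
  cvm <- colMeans(err, na.rm = TRUE)
  k <- sum(!is.na(err[, 1L]))
  cvse <- apply(err, 2L, function(e) sd(e, na.rm = TRUE)) / sqrt(max(k, 1L))
  i_min <- which.min(cvm)
  i_sel <- if (penalty$rule == "1se") {
    # sparsest (largest) lambda whose CV error is within 1 SE of the minimum
    min(which(cvm <= cvm[i_min] + cvse[i_min]))
  } else i_min
  list(lambda = grid[i_sel], grid = grid, cvm = cvm, cvse = cvse,
       index = i_sel)
}
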
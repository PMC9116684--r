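#' Classifier configuration
#'
#' @param kind `"ksvm"` (RBF-kernel support vector machine, the dual
#'   maximum-margin problem solved as a quadratic program), `"rf"` (random
#'   forest of CART trees grown on bootstrapped samples, majority vote) or
#'   `"dnn"` (six-hidden-layer fully connected feed-forward network, ReLU
#'   hidden activations, soft-max output).
#' @param rbf_sigma RBF width. `"auto"` (default) uses the scale heuristic
#'   `gamma = 1 / (n_features * Var(x))` for the kernel
#'   `exp(-gamma * ||r - r'||^2)`, i.e. `sigma = sqrt(1 / (2 * gamma))`.
#' @param svm_cost Soft-margin cost C.
#' @param n_trees Number of trees B.
#' @param features_per_split `"sqrt"`, `"log2"`, `"all"` or an integer:
#'   features considered at each split.
#' @param max_depth,min_node Tree growth limits.
#' @param hidden_layers Six hidden-layer widths (tapering 512 to 16 by
#'   default).
#' @param epochs,learning_rate Full-batch Adam training schedule for the
#'   network.
#' @param seed Seed for the classifier's own randomness (bootstraps,
#'   weight initialisation).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(kind = c("ksvm", "rf", "dnn"),
                              rbf_sigma = "auto", svm_cost = 1,
                              n_trees = 500L, features_per_split = "sqrt",
                              max_depth = 10L, min_node = 2L,
                              hidden_layers = c(512L, 256L, 128L, 64L, 32L, 16L),
                              epochs = 100L, learning_rate = 1e-3,
                              seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "dnn" && length(hidden_layers) != 6L)
    stop("the network uses exactly six hidden layers")
  if (!identical(rbf_sigma, "auto") &&
      (!is.numeric(rbf_sigma) || rbf_sigma <= 0))
    stop("rbf_sigma must be 'auto' or a positive number")
  if (svm_cost <= 0) stop("svm_cost must be positive")
  structure(list(kind = kind, rbf_sigma = rbf_sigma, svm_cost = svm_cost,
                 n_trees = as.integer(n_trees),
                 features_per_split = features_per_split,
                 max_depth = as.integer(max_depth),
                 min_node = as.integer(min_node),
                 hidden_layers = as.integer(hidden_layers),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Train a sensitive/resistant classifier on regulatory-effect features
#'
#' @param features A `feature_matrix` (rows: sensitive/resistant samples;
#'   label 1 = sensitive).
#' @param config A [classifier_config()].
#' @return An `xpred_model` usable with [predict()] on matrices with the
#'   same columns.
#' @export
train_classifier <- function(features, config) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(config, "classifier_config"))
  x <- features$x; y <- features$y
  if (length(unique(y)) < 2L) stop("single-class input: cannot train")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  fit <- switch(config$kind,
    ksvm = ksvm_train(x, y, config),
    rf = withr::with_seed(config$seed, rf_train(x, y, config)),
    dnn = withr::with_seed(config$seed, dnn_train(x, y, config)))
  structure(list(kind = config$kind, fit = fit, config = config,
                 columns = colnames(x)),
            class = "xpred_model")
}

#' @export
predict.xpred_model <- function(object, newx, ...) {
  if (inherits(newx, "feature_matrix")) newx <- newx$x
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$columns))
    stop("new data has a different column map than the training data")
  switch(object$kind,
    ksvm = ksvm_predict(object$fit, newx),
    rf = rf_predict(object$fit, newx),
    dnn = dnn_predict(object$fit, newx))
}

## ---- kernel SVM (dual QP, RBF kernel) --------------------------------

rbf_gamma <- function(x, rbf_sigma) {
  if (identical(rbf_sigma, "auto")) {
    # scale heuristic gamma = 1 / (p * Var), with the uncentered second
    # moment as the variance: p then cancels, so deleting an identically
    # zero feature column provably leaves the kernel matrix unchanged.
    pv <- sum(x^2) / nrow(x)
    if (!is.finite(pv) || pv <= 0) return(1 / ncol(x))
    1 / pv
  } else {
    1 / (2 * rbf_sigma^2)
  }
}

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

ksvm_train <- function(x, y, config) {
  yy <- ifelse(y == 1L, 1, -1)
  n <- nrow(x)
  gamma <- rbf_gamma(x, config$rbf_sigma)
  K <- rbf_kernel(x, x, gamma)
  C <- config$svm_cost
  D0 <- (yy %o% yy) * K
  A <- cbind(yy, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- NULL
  for (ridge in c(1e-8, 1e-6, 1e-4, 1e-2)) { # near-duplicate rows make K
    D <- D0; diag(D) <- diag(D) + ridge      # near-singular; escalate
    sol <- tryCatch(quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1L),
                    error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol)) stop("SVM dual QP failed even with ridge 1e-2")
  delta <- pmin(pmax(sol$solution, 0), C)
  sv <- which(delta > 1e-8)
  f_no_b <- as.numeric(K %*% (delta * yy))
  margin <- which(delta > 1e-7 & delta < C - 1e-7)
  b <- if (length(margin)) mean(yy[margin] - f_no_b[margin])
       else if (length(sv)) mean(yy[sv] - f_no_b[sv]) else 0
  list(sv_x = x[sv, , drop = FALSE], sv_coef = (delta * yy)[sv],
       bias = b, gamma = gamma)
}

ksvm_decision <- function(fit, newx) {
  if (nrow(fit$sv_x) == 0L) return(rep(fit$bias, nrow(newx)))
  as.numeric(rbf_kernel(newx, fit$sv_x, fit$gamma) %*% fit$sv_coef) + fit$bias
}

ksvm_predict <- function(fit, newx) {
  as.integer(ksvm_decision(fit, newx) >= 0)
}

## ---- random forest (CART, gini, bootstrap + per-split feature draw) ---

mtry_size <- function(rule, p) {
  if (is.numeric(rule)) return(max(1L, min(p, as.integer(rule))))
  switch(rule,
    sqrt = max(1L, floor(sqrt(p))),
    log2 = max(1L, floor(log2(p))),
    all = p,
    stop("unknown features_per_split rule: ", rule))
}

gini_split <- function(v, y) {
  # best threshold for one feature; returns c(score, threshold) or NULL
  ord <- order(v)
  vs <- v[ord]; ys <- y[ord]
  n <- length(ys)
  cut_at <- which(diff(vs) > 0)
  if (!length(cut_at)) return(NULL)
  pos_left <- cumsum(ys)[cut_at]
  n_left <- cut_at
  n_right <- n - n_left
  pos_right <- sum(ys) - pos_left
  p1 <- pos_left / n_left; p2 <- pos_right / n_right
  score <- (n_left * 2 * p1 * (1 - p1) + n_right * 2 * p2 * (1 - p2)) / n
  i <- which.min(score)
  c(score[i], (vs[cut_at[i]] + vs[cut_at[i] + 1L]) / 2)
}

grow_tree <- function(x, y, depth, config) {
  n1 <- sum(y); n0 <- length(y) - n1
  leaf <- list(leaf = TRUE, class = if (n1 >= n0) 1L else 0L)
  if (depth >= config$max_depth || length(y) < 2L * config$min_node ||
      n1 == 0L || n0 == 0L)
    return(leaf)
  p <- ncol(x)
  feats <- sort(sample.int(p, mtry_size(config$features_per_split, p)))
  best <- NULL
  for (j in feats) {
    s <- gini_split(x[, j], y)
    if (!is.null(s) && (is.null(best) || s[1L] < best$score))
      best <- list(score = s[1L], feature = j, threshold = s[2L])
  }
  if (is.null(best)) return(leaf)
  left <- x[, best$feature] <= best$threshold
  if (sum(left) < config$min_node || sum(!left) < config$min_node)
    return(leaf)
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(x[left, , drop = FALSE], y[left], depth + 1L, config),
       right = grow_tree(x[!left, , drop = FALSE], y[!left], depth + 1L,
                         config))
}

tree_predict <- function(tree, x) {
  out <- integer(nrow(x))
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    left <- x[idx, node$feature] <= node$threshold
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(tree, seq_len(nrow(x)))
  out
}

rf_train <- function(x, y, config) {
  trees <- vector("list", config$n_trees)
  n <- nrow(x)
  for (b in seq_len(config$n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(x[idx, , drop = FALSE], y[idx], 0L, config)
  }
  list(trees = trees)
}

rf_predict <- function(fit, newx) {
  votes <- rowSums(vapply(fit$trees, tree_predict, integer(nrow(newx)),
                          x = newx))
  as.integer(votes >= length(fit$trees) / 2)
}

## ---- feed-forward network (6 hidden ReLU layers, soft-max output) -----

dnn_train <- function(x, y, config) {
  sizes <- c(ncol(x), config$hidden_layers, 2L)
  nl <- length(sizes) - 1L
  W <- vector("list", nl); bvec <- vector("list", nl)
  for (k in seq_len(nl)) { # He initialisation
    W[[k]] <- matrix(rnorm(sizes[k] * sizes[k + 1L],
                           sd = sqrt(2 / sizes[k])),
                     sizes[k], sizes[k + 1L])
    bvec[[k]] <- numeric(sizes[k + 1L])
  }
  targets <- cbind(1 - y, y) # column 2 = sensitive
  n <- nrow(x)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(bvec, function(b) b * 0); vb <- mb
  lr <- config$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(config$epochs)) { # full-batch Adam
    acts <- vector("list", nl + 1L); acts[[1L]] <- x
    for (k in seq_len(nl)) {
      z <- sweep(acts[[k]] %*% W[[k]], 2L, bvec[[k]], "+")
      acts[[k + 1L]] <- if (k < nl) pmax(z, 0) else z
    }
    logits <- acts[[nl + 1L]]
    pm <- exp(logits - apply(logits, 1L, max))
    pm <- pm / rowSums(pm)
    delta <- (pm - targets) / n
    for (k in rev(seq_len(nl))) {
      gW <- crossprod(acts[[k]], delta)
      gb <- colSums(delta)
      if (k > 1L)
        delta <- (delta %*% t(W[[k]])) * (acts[[k]] > 0)
      mW[[k]] <- b1 * mW[[k]] + (1 - b1) * gW
      vW[[k]] <- b2 * vW[[k]] + (1 - b2) * gW^2
      mb[[k]] <- b1 * mb[[k]] + (1 - b1) * gb
      vb[[k]] <- b2 * vb[[k]] + (1 - b2) * gb^2
      corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
      W[[k]] <- W[[k]] - lr * (mW[[k]] / corr1) /
        (sqrt(vW[[k]] / corr2) + eps)
      bvec[[k]] <- bvec[[k]] - lr * (mb[[k]] / corr1) /
        (sqrt(vb[[k]] / corr2) + eps)
    }
  }
  list(W = W, b = bvec)
}

dnn_predict <- function(fit, newx) {
  a <- newx
  nl <- length(fit$W)
  for (k in seq_len(nl)) {
    z <- sweep(a %*% fit$W[[k]], 2L, fit$b[[k]], "+")
    a <- if (k < nl) pmax(z, 0) else z
  }
  as.integer(a[, 2L] >= a[, 1L]) # tie goes to the sensitive class
}
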
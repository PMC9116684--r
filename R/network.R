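# Local (anchor-specific) fit with weighted standardisation.
#
# Predictors and response are centred and scaled by their kernel-weighted
# means/SDs before fitting (this absorbs the intercept the structural model
# omits and makes the penalty scale-free); coefficients are returned on the
# original scale. Zero-variance columns under the weights get coefficient 0.
fit_local <- function(X, y, w, penalty, tol = 1e-6, max_iter = 10000L,
                      lambda_ratio = NULL) {
  u <- w / sum(w)
  mu_x <- as.numeric(crossprod(u, X))
  sd_x <- sqrt(as.numeric(crossprod(u, X^2)) - mu_x^2)
  mu_y <- sum(u * y)
  sd_y <- sqrt(sum(u * y^2) - mu_y^2)
  keep <- which(sd_x > 1e-10)
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  if (length(keep) == 0L || sd_y <= 1e-10) return(beta)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu_x[keep]), 2L,
              sd_x[keep], "/")
  ys <- (y - mu_y) / sd_y
  lambda <- if (!is.null(lambda_ratio)) {
    lambda_ratio * lambda_max_value(Xs, ys, w, penalty$mixing)
  } else if (!is.null(penalty$lambda)) {
    penalty$lambda
  } else {
    cv_lambda(Xs, ys, w, penalty, tol, max_iter)$lambda
  }
  bs <- fit_weighted_elastic_net(Xs, ys, w, lambda, penalty$mixing,
                                 tol = tol, max_iter = max_iter)
  b <- bs * sd_y / sd_x[keep]
  b[abs(b) < 1e-12] <- 0
  beta[keep] <- b
  beta
}

#' Select a per-target kernel bandwidth
#'
#' Chooses, from a candidate grid, the bandwidth minimising the
#' leave-one-out prediction error of the local fit averaged over anchor
#' samples: for each anchor, the local model is fitted on all other samples
#' with kernel weights centred at the anchor's modulator value and used to
#' predict the anchor's response. Ties go to the smallest candidate. The
#' local fits use a fixed penalty at `lambda_ratio` of the local
#' `lambda_max` (full CV inside bandwidth selection would be quadratic in
#' cost).
#'
#' @param modulator Per-sample modulator values.
#' @param candidates Positive candidate bandwidths (>= 1).
#' @param X n x p predictor matrix (regulator expression).
#' @param y Length-n response (target expression).
#' @param penalty A [penalty_config()] (only `mixing` is used).
#' @param anchors Optional anchor indices over which the LOO error is
#'   averaged; default: up to `max_anchors` samples evenly spaced in
#'   modulator rank (deterministic).
#' @param max_anchors Cap on the default anchor set.
#' @param lambda_ratio Fraction of the local `lambda_max` used for the LOO
#'   fits.
#' @return The selected bandwidth, with the per-candidate LOO errors as
#'   attribute `"loo_error"`.
#' @export
select_bandwidth <- function(modulator, candidates, X, y,
                             penalty = penalty_config(), anchors = NULL,
                             max_anchors = 40L, lambda_ratio = 0.1) {
  if (length(candidates) == 0L) stop("empty bandwidth candidate list")
  if (any(candidates <= 0)) stop("bandwidth candidates must be positive")
  candidates <- sort(candidates)
  if (length(candidates) == 1L) return(candidates)
  n <- length(modulator)
  if (is.null(anchors)) {
    k <- min(n, max_anchors)
    anchors <- order(modulator)[unique(round(seq(1L, n, length.out = k)))]
  }
  X <- as.matrix(X)
  err <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    b <- candidates[ci]
    se <- 0
    for (a in anchors) {
      w <- gaussian_kernel(modulator, modulator[a], b)
      beta <- fit_local(X[-a, , drop = FALSE], y[-a], w[-a], penalty,
                        lambda_ratio = lambda_ratio)
      u <- w[-a] / sum(w[-a])
      mu_x <- as.numeric(crossprod(u, X[-a, , drop = FALSE]))
      mu_y <- sum(u * y[-a])
      pred <- mu_y + sum((X[a, ] - mu_x) * beta)
      se <- se + (y[a] - pred)^2
    }
    err[ci] <- se / length(anchors)
  }
  sel <- candidates[which.min(err)] # which.min takes the first = smallest tie
  attr(sel, "loo_error") <- stats::setNames(err, candidates)
  sel
}

default_bandwidth_grid <- function(modulator) {
  c(0.25, 0.5, 1, 2, 4) * var(modulator)
}

#' Estimate one sample's regulatory-coefficient row for one target
#'
#' Kernel weights are computed from the modulator drug's sensitivities
#' anchored at `anchor`; the weighted elastic net is fitted on
#' weighted-standardised data and the coefficients returned on the original
#' scale. The target gene is excluded from its own predictor set.
#'
#' @param dataset An `aligned_dataset`.
#' @param modulator_drug Drug id whose sensitivity is the modulator.
#' @param target Target gene id.
#' @param anchor Anchor sample id.
#' @param penalty A [penalty_config()]; a fixed `lambda` applies on the
#'   standardised scale, otherwise lambda is selected by kernel-weighted CV.
#' @param bandwidth Positive kernel bandwidth for this target.
#' @return Named coefficient vector over `dataset$regulator_ids` (exact
#'   zeros for absent edges; the self-loop entry is 0 by construction).
#' @export
estimate_sample_network <- function(dataset, modulator_drug, target, anchor,
                                    penalty = penalty_config(), bandwidth) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  if (!target %in% dataset$target_ids) stop("unknown target: ", target)
  if (!anchor %in% dataset$sample_ids) stop("unknown anchor sample: ", anchor)
  m <- dataset$sensitivity[, modulator_drug]
  w <- gaussian_kernel(m, m[[anchor]], bandwidth)
  regs <- setdiff(dataset$regulator_ids, target)
  X <- t(dataset$expression[regs, , drop = FALSE])
  y <- dataset$expression[target, ]
  beta <- fit_local(X, y, w, penalty)
  out <- stats::setNames(numeric(length(dataset$regulator_ids)),
                         dataset$regulator_ids)
  out[regs] <- beta
  out
}

#' Estimate the full stack of per-sample networks
#'
#' One network per sample: for every (target, anchor sample) pair the
#' varying coefficients are estimated at the anchor's modulator value.
#' Samples with identical modulator values receive identical coefficient
#' rows (they induce identical kernel weights), and this is exploited so
#' each unique modulator value is fitted once. Output is deterministic.
#'
#' @inheritParams estimate_sample_network
#' @param targets Target gene ids (default: the dataset's target set).
#' @param bandwidth `"select"` (per-target [select_bandwidth()] over
#'   `bandwidth_grid`), a single number, or a named per-target vector.
#' @param bandwidth_grid Candidate grid for `"select"`; default
#'   `{0.25, 0.5, 1, 2, 4} * var(modulator)`.
#' @param verbose Print per-target progress.
#' @return A `network_stack`: list with `coefficients` (n x L x J array,
#'   absent edges exactly 0), `bandwidths`, id vectors, `modulator_drug`
#'   and the penalty used.
#' @export
estimate_all_networks <- function(dataset, modulator_drug,
                                  targets = dataset$target_ids,
                                  penalty = penalty_config(),
                                  bandwidth = "select",
                                  bandwidth_grid = NULL,
                                  verbose = FALSE) {
  stopifnot(inherits(dataset, "aligned_dataset"), length(targets) >= 1L)
  m <- dataset$sensitivity[, modulator_drug]
  n <- length(m)
  samples <- dataset$sample_ids
  regs_all <- dataset$regulator_ids
  if (is.null(bandwidth_grid)) bandwidth_grid <- default_bandwidth_grid(m)

  coefs <- array(0, dim = c(n, length(targets), length(regs_all)),
                 dimnames = list(samples, targets, regs_all))
  bws <- stats::setNames(numeric(length(targets)), targets)

  for (li in seq_along(targets)) {
    target <- targets[li]
    regs <- setdiff(regs_all, target)
    X <- t(dataset$expression[regs, , drop = FALSE])
    y <- dataset$expression[target, ]
    b <- if (identical(bandwidth, "select")) {
      as.numeric(select_bandwidth(m, bandwidth_grid, X, y, penalty))
    } else if (is.numeric(bandwidth) && !is.null(names(bandwidth))) {
      bandwidth[[target]]
    } else {
      as.numeric(bandwidth)
    }
    bws[target] <- b
    if (verbose) message("target ", target, ": bandwidth ", signif(b, 3))
    seen <- new.env(parent = emptyenv())
    for (a in seq_len(n)) {
      key <- sprintf("%.17g", m[a])
      row <- get0(key, envir = seen)
      if (is.null(row)) {
        w <- gaussian_kernel(m, m[a], b)
        row <- fit_local(X, y, w, penalty)
        assign(key, row, envir = seen)
      }
      coefs[a, li, regs] <- row
    }
  }
  structure(list(coefficients = coefs, bandwidths = bws,
                 sample_ids = samples, target_ids = targets,
                 regulator_ids = regs_all,
                 modulator_drug = modulator_drug, penalty = penalty),
            class = "network_stack")
}

#' @export
print.network_stack <- function(x, ...) {
  d <- dim(x$coefficients)
  cat("network_stack:", d[1L], "sample networks,", d[2L], "targets x",
      d[3L], "regulators\n")
  cat("  modulator drug:", x$modulator_drug,
      " nonzero coefficients:", sum(x$coefficients != 0), "\n")
  invisible(x)
}

#' Flatten a network stack to an edge list
#'
#' @param stack A `network_stack`.
#' @param tol Coefficients with absolute value `<= tol` are treated as
#'   absent.
#' @return Edge-list data frame (`target`, `regulator`, `weight`,
#'   `sample`).
#' @export
stack_edge_list <- function(stack, tol = 0) {
  idx <- which(abs(stack$coefficients) > tol, arr.ind = TRUE)
  out <- data.frame(
    target = stack$target_ids[idx[, 2L]],
    regulator = stack$regulator_ids[idx[, 3L]],
    weight = stack$coefficients[idx],
    sample = stack$sample_ids[idx[, 1L]],
    stringsAsFactors = FALSE)
  out[order(out$sample, out$target, out$regulator), , drop = FALSE]
}
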
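#' Simulation configuration
#'
#' Describes a synthetic world matching the varying-coefficient model the
#' network estimator assumes: target expression is a sparse linear
#' combination of regulator expression whose coefficients change smoothly
#' with a continuous per-sample modulator (a drug-sensitivity score), plus
#' Gaussian noise. A planted subset of genes has dependency scores
#' correlated with the modulator so the dependency-correlation filter can
#' recover them.
#'
#' Coefficient profiles over the modulator m (all smooth logistic ramps, so
#' kernel-local estimation is well posed):
#' \describe{
#'   \item{constant}{beta(m) = a.}
#'   \item{increasing}{beta(m) = a * logistic(m / 0.5).}
#'   \item{sensitive_only}{beta(m) ~ a below the theoretical 10th percentile
#'     of the modulator, tapering smoothly to 0 above it.}
#'   \item{resistant_only}{mirror image: active above the 90th percentile.}
#' }
#'
#' @param n_samples,n_regulators,n_targets Dimensions (all >= 1).
#' @param edge_density Fraction of (target, regulator) pairs with a truly
#'   nonzero coefficient function.
#' @param noise_sd Standard deviation of the additive expression noise
#'   (>= 0; 0 gives the noiseless limit).
#' @param n_crucial_edges Number of support edges given modulator-switched
#'   profiles (`crucial_profile`) so that they drive the
#'   sensitive/resistant labels.
#' @param crucial_profile Profile tag(s) for the crucial edges, recycled.
#'   Default `"sensitive_only"`: same-direction planted edges give every
#'   planted edge a well-defined positive contribution to prediction
#'   accuracy, which is what an importance-recovery benchmark needs;
#'   mixed-direction designs (pass
#'   `c("sensitive_only", "resistant_only")`) create conflicting kernel
#'   geometry in which ablating a planted edge can even improve accuracy.
#' @param coefficient_profile Profile tag(s) for the remaining support
#'   edges, recycled ("constant", "increasing", "sensitive_only",
#'   "resistant_only").
#' @param modulator_distribution Only `"normal"` (standard normal) is
#'   implemented.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @param amplitude_range Range of absolute edge amplitudes `a` (random
#'   sign) for non-crucial support edges.
#' @param crucial_amplitude Absolute amplitude of the crucial
#'   (label-driving) edges. Default 3: on the standardised expression scale
#'   a crucial regulatory effect about three times the background edge
#'   amplitude puts end-to-end classification in the high-accuracy regime
#'   the method is designed for while leaving each planted edge
#'   individually informative.
#' @param dependency_effect Slope `a` of the planted dependency signal
#'   `a * m + N(0, 1)` given to every target gene.
#' @param response_cor Correlation between the modulator drug ("drug_A")
#'   and the second, response drug ("drug_B") in the sensitivity table.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples, n_regulators, n_targets,
                              edge_density = 0.1, noise_sd = 0.5,
                              n_crucial_edges = 0L,
                              crucial_profile = "sensitive_only",
                              coefficient_profile = "constant",
                              modulator_distribution = "normal",
                              seed = 1L,
                              amplitude_range = c(0.5, 1.5),
                              crucial_amplitude = 3,
                              dependency_effect = 1,
                              response_cor = 0.8) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_regulators = as.integer(n_regulators),
              n_targets = as.integer(n_targets),
              edge_density = edge_density, noise_sd = noise_sd,
              n_crucial_edges = as.integer(n_crucial_edges),
              crucial_profile = crucial_profile,
              coefficient_profile = coefficient_profile,
              modulator_distribution = modulator_distribution,
              seed = as.integer(seed),
              amplitude_range = amplitude_range,
              crucial_amplitude = crucial_amplitude,
              dependency_effect = dependency_effect,
              response_cor = response_cor)
  with(cfg, {
    if (n_samples < 1L || n_regulators < 1L || n_targets < 1L)
      stop("all counts must be >= 1")
    if (edge_density <= 0 || edge_density > 1)
      stop("edge_density must be in (0, 1]")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    n_edges <- round(edge_density * n_regulators * n_targets)
    if (n_crucial_edges > n_edges)
      stop("n_crucial_edges exceeds the support size ", n_edges)
    if (!all(coefficient_profile %in% profile_names()) ||
        !all(crucial_profile %in% c("sensitive_only", "resistant_only")))
      stop("unknown coefficient profile")
    if (modulator_distribution != "normal")
      stop("only the standard-normal modulator is implemented")
    if (abs(response_cor) > 1) stop("response_cor must be in [-1, 1]")
  })
  structure(cfg, class = "simulation_config")
}

profile_names <- function() {
  c("constant", "increasing", "sensitive_only", "resistant_only")
}

# Tabulated coefficient function for one edge. Ramp scales are fixed model
# constants: 0.5 for the global "increasing" ramp, 0.25 for the percentile
# switches (sharp enough that the edge is essentially absent in the other
# class, smooth enough for kernel-local estimation).
profile_fun <- function(profile, amplitude) {
  q10 <- stats::qnorm(0.1)
  q90 <- stats::qnorm(0.9)
  switch(profile,
    constant = function(m) rep(amplitude, length(m)),
    increasing = function(m) amplitude * stats::plogis(m / 0.5),
    sensitive_only = function(m) amplitude * stats::plogis((q10 - m) / 0.25),
    resistant_only = function(m) amplitude * stats::plogis((m - q90) / 0.25),
    stop("unknown profile: ", profile))
}

#' Simulate an aligned dataset with full ground truth
#'
#' Draws regulator expression i.i.d. standard normal, evaluates the true
#' coefficient functions at each sample's modulator value, and generates
#' target expression from the linear varying-coefficient model with
#' Gaussian noise. The sensitivity table carries the modulator as
#' `"drug_A"` plus a correlated second drug `"drug_B"`; the dependency
#' matrix gives every target gene a planted `a * m + N(0,1)` signal.
#'
#' @param config A [simulation_config()].
#' @return List with components `dataset` (an `aligned_dataset`) and
#'   `truth` (a `ground_truth` list: `beta_array` (n x L x J true
#'   coefficients at each sample's modulator), `support` and
#'   `crucial_edges` data frames, `beta_grid` tabulation, `true_labels`,
#'   `modulator`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_samples; J <- cfg$n_regulators; L <- cfg$n_targets
  reg_ids <- sprintf("REG%03d", seq_len(J))
  tgt_ids <- sprintf("TGT%03d", seq_len(L))
  sample_ids <- sprintf("S%04d", seq_len(n))

  m <- rnorm(n)

  # sparse support and per-edge profiles
  n_edges <- round(cfg$edge_density * L * J)
  all_pairs <- expand.grid(target = seq_len(L), regulator = seq_len(J))
  support_idx <- sample(nrow(all_pairs), n_edges)
  support <- all_pairs[support_idx, , drop = FALSE]
  rownames(support) <- NULL
  nc <- cfg$n_crucial_edges
  profs <- character(n_edges)
  if (nc > 0L)
    profs[seq_len(nc)] <- rep_len(cfg$crucial_profile, nc)
  if (n_edges > nc)
    profs[(nc + 1L):n_edges] <- rep_len(cfg$coefficient_profile, n_edges - nc)
  amp <- runif(n_edges, cfg$amplitude_range[1L], cfg$amplitude_range[2L]) *
    sample(c(-1, 1), n_edges, replace = TRUE)
  if (nc > 0L) amp[seq_len(nc)] <- cfg$crucial_amplitude * sign(amp[seq_len(nc)])
  support$profile <- profs
  support$amplitude <- amp
  support$target_id <- tgt_ids[support$target]
  support$regulator_id <- reg_ids[support$regulator]

  # true coefficients at each sample's modulator value
  beta_array <- array(0, dim = c(n, L, J),
                      dimnames = list(sample_ids, tgt_ids, reg_ids))
  grid <- seq(-3, 3, length.out = 121L)
  beta_grid <- array(0, dim = c(121L, L, J),
                     dimnames = list(NULL, tgt_ids, reg_ids))
  for (e in seq_len(n_edges)) {
    f <- profile_fun(support$profile[e], support$amplitude[e])
    beta_array[, support$target[e], support$regulator[e]] <- f(m)
    beta_grid[, support$target[e], support$regulator[e]] <- f(grid)
  }

  X <- matrix(rnorm(n * J), n, J, dimnames = list(sample_ids, reg_ids))
  Y <- matrix(0, n, L, dimnames = list(sample_ids, tgt_ids))
  for (l in seq_len(L)) {
    bl <- beta_array[, l, , drop = FALSE]
    dim(bl) <- c(n, J)
    Y[, l] <- rowSums(bl * X) + rnorm(n, sd = cfg$noise_sd)
  }

  expr <- t(cbind(Y, X)) # genes x samples: targets first, then regulators

  rc <- cfg$response_cor
  sens <- cbind(drug_A = m,
                drug_B = rc * m + sqrt(max(0, 1 - rc^2)) * rnorm(n))
  rownames(sens) <- sample_ids

  dep <- matrix(rnorm((L + J) * n), L + J, n,
                dimnames = list(c(tgt_ids, reg_ids), sample_ids))
  dep[tgt_ids, ] <- dep[tgt_ids, ] +
    rep(cfg$dependency_effect * m, each = L)

  dataset <- align_samples(expr, sens, dep, drug_ids = c("drug_A", "drug_B"),
                           regulator_ids = reg_ids, target_ids = tgt_ids)

  truth <- structure(
    list(beta_array = beta_array, beta_grid = beta_grid,
         beta_grid_modulator = grid,
         support = support,
         crucial_edges = support[seq_len(nc), c("target_id", "regulator_id"),
                                 drop = FALSE],
         true_labels = if (n >= 10L) simulate_labels(m) else
           stats::setNames(rep("intermediate", n), sample_ids),
         modulator = stats::setNames(m, sample_ids),
         config = cfg),
    class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Label a simulated modulator by its empirical percentiles
#'
#' Delegates to the same percentile rule used for real drug-sensitivity
#' tables ([label_sensitivity()]): sensitive below the `p_low`th empirical
#' percentile, resistant above the `p_high`th, strict inequalities, linear
#' interpolation between order statistics.
#'
#' @param modulator Per-sample numeric modulator values.
#' @param p_low,p_high Percentile cut points (defaults 10 and 90).
#' @return Character vector in `{"sensitive", "resistant", "intermediate"}`.
#' @export
simulate_labels <- function(modulator, p_low = 10, p_high = 90) {
  ids <- names(modulator)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_along(modulator))
  sens <- matrix(modulator, ncol = 1L, dimnames = list(ids, "drug"))
  label_sensitivity(sens, "drug", p_low = p_low, p_high = p_high)$labels
}

#' True regulatory-effect tensor of a simulation
#'
#' Evaluates coefficient-times-expression on the ground-truth coefficients
#' (raw expression scale), giving the noise-free feature tensor that the
#' estimation pipeline tries to recover. Used by tests and calibration
#' studies.
#'
#' @param sim Result of [simulate_dataset()].
#' @return A `re_tensor` (same class as [compute_regulatory_effects()]).
#' @export
true_regulatory_effects <- function(sim) {
  truth <- sim$truth; dataset <- sim$dataset
  X <- t(dataset$expression[dataset$regulator_ids, , drop = FALSE])
  values <- truth$beta_array
  d <- dim(values)
  for (l in seq_len(d[2L])) {
    bl <- values[, l, , drop = FALSE]
    dim(bl) <- c(d[1L], d[3L])
    values[, l, ] <- bl * X
  }
  structure(list(values = values,
                 sample_ids = dimnames(values)[[1L]],
                 target_ids = dimnames(values)[[2L]],
                 regulator_ids = dimnames(values)[[3L]],
                 modulator_drug = "drug_A"),
            class = "re_tensor")
}
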
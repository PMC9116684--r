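# Shared fixture builders: everything is generated in code at test time.

toy_matrix <- function(nr, nc, seed = 1, prefix = c("G", "S")) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc,
         dimnames = list(sprintf("%s%02d", prefix[1L], seq_len(nr)),
                         sprintf("%s%02d", prefix[2L], seq_len(nc))))
}

# A feature_matrix built directly from a numeric matrix and 0/1 labels.
make_features <- function(x, y, n_targets = NULL) {
  p <- ncol(x)
  if (is.null(n_targets)) n_targets <- 1L
  stopifnot(p %% n_targets == 0L)
  per <- p / n_targets
  cm <- data.frame(column = seq_len(p),
                   target = paste0("T", rep(seq_len(n_targets), each = per)),
                   regulator = paste0("R", rep(seq_len(per), n_targets)),
                   stringsAsFactors = FALSE)
  colnames(x) <- paste(cm$target, cm$regulator, sep = "|")
  rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  structure(list(x = x, y = stats::setNames(as.integer(y), rownames(x)),
                 column_map = cm, modulator_drug = "drug_A",
                 response_drug = "drug_B"),
            class = "feature_matrix")
}

# Small simulated world reused across tests.
small_sim <- function(seed = 1, n = 60, J = 6, L = 3, density = 0.25,
                      noise_sd = 0.3, crucial = 0L, profile = "constant") {
  cfg <- simulation_config(n, J, L, edge_density = density,
                           noise_sd = noise_sd, n_crucial_edges = crucial,
                           coefficient_profile = profile, seed = seed)
  suppressMessages(simulate_dataset(cfg))
}

# A tiny hand-built network stack.
make_stack <- function(coefs, modulator_drug = "drug_A") {
  dn <- dimnames(coefs)
  structure(list(coefficients = coefs,
                 bandwidths = stats::setNames(rep(1, dim(coefs)[2L]), dn[[2L]]),
                 sample_ids = dn[[1L]], target_ids = dn[[2L]],
                 regulator_ids = dn[[3L]], modulator_drug = modulator_drug,
                 penalty = penalty_config()),
            class = "network_stack")
}

make_tensor <- function(values, modulator_drug = "drug_A") {
  dn <- dimnames(values)
  structure(list(values = values, sample_ids = dn[[1L]],
                 target_ids = dn[[2L]], regulator_ids = dn[[3L]],
                 modulator_drug = modulator_drug),
            class = "re_tensor")
}

make_labels <- function(labels, drug = "drug_B", lo = -1, hi = 1) {
  structure(list(labels = labels, p_low_value = lo, p_high_value = hi,
                 p_low = 10, p_high = 90, response_drug = drug,
                 counts = table(labels)),
            class = "sensitivity_labels")
}
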
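test_that("gaussian kernel matches its closed form", {
  expect_identical(gaussian_kernel(1.7, 1.7, 0.3), 1)
  # squared distance equal to the bandwidth gives exp(-1)
  expect_equal(gaussian_kernel(2, 2 + sqrt(0.5), 0.5), exp(-1))
  expect_equal(gaussian_kernel(0, 3, 2), exp(-9 / 2))
  expect_equal(gaussian_kernel(3, 0, 2), gaussian_kernel(0, 3, 2))
  # weight increases to 1 monotonically as b grows
  w <- sapply(c(1, 10, 100, 1e6), function(b) gaussian_kernel(0, 1, b))
  expect_true(all(diff(w) > 0) && w[4] > 0.999)
  expect_error(gaussian_kernel(0, 1, 0), "positive")
  expect_error(gaussian_kernel(0, 1, -2), "positive")
})

test_that("kernel_weights anchors at weight 1 and decays with distance", {
  m <- c(S1 = 0.2, S2 = -1, S3 = 2, S4 = 0.3)
  kw <- kernel_weights(m, "S1", 1)
  expect_s3_class(kw, "kernel_weights")
  expect_identical(kw$weights[["S1"]], 1)
  ord <- order(abs(m - m["S1"]))
  expect_true(all(diff(kw$weights[ord]) <= 0))
})

test_that("lambda = 0 reproduces the weighted least-squares closed form", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(100), 20, 5); y <- rnorm(20); w <- runif(20, 0.1, 1)
    b <- fit_weighted_elastic_net(X, y, w, lambda = 0, tol = 1e-10)
    oracle <- solve(crossprod(X, w * X), crossprod(X, w * y))
    expect_lt(max(abs(b - oracle)), 1e-8)
  }
})

test_that("lambda at or above lambda_max forces the zero vector", {
  set.seed(11)
  X <- matrix(rnorm(120), 30, 4); y <- rnorm(30); w <- runif(30, 0.2, 1)
  mixing <- 0.7
  lmax <- max(abs(crossprod(X, w * y))) / mixing
  expect_identical(unname(fit_weighted_elastic_net(X, y, w, lmax, mixing)),
                   rep(0, 4))
  expect_identical(unname(fit_weighted_elastic_net(X, y, w, 2 * lmax, mixing)),
                   rep(0, 4))
  # just below lambda_max at least one coefficient activates
  expect_gt(sum(fit_weighted_elastic_net(X, y, w, 0.95 * lmax, mixing) != 0), 0)
})

test_that("coordinate descent matches a generic minimizer's objective", {
  for (s in 1:5) {
    set.seed(100 + s)
    X <- matrix(rnorm(100), 20, 5); y <- rnorm(20); w <- runif(20, 0.1, 1)
    b <- fit_weighted_elastic_net(X, y, w, 0.1, 0.5, tol = 1e-9)
    obj <- function(beta) weighted_elastic_net_objective(X, y, w, beta, 0.1, 0.5)
    nm <- optim(rep(0, 5), obj, method = "Nelder-Mead",
                control = list(maxit = 20000, reltol = 1e-13))
    expect_lt(obj(b) - nm$value, 1e-6)
  }
})

test_that("the objective never increases across sweeps", {
  for (s in 1:10) {
    set.seed(200 + s)
    X <- matrix(rnorm(30 * 8), 30, 8); y <- rnorm(30); w <- runif(30)
    b <- fit_weighted_elastic_net(X, y, w, runif(1, 0.01, 1), runif(1),
                                  trace = TRUE)
    tr <- attr(b, "objective_trace")
    expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("degenerate penalty inputs error out", {
  X <- matrix(rnorm(20), 10, 2); y <- rnorm(10)
  expect_error(fit_weighted_elastic_net(X, y, rep(0, 10), 0.1), "weights")
  expect_error(fit_weighted_elastic_net(X, y, rep(1, 10), -1), "lambda")
  expect_error(fit_weighted_elastic_net(X[1, , drop = FALSE], y[1], 1, 0.1),
               "2 samples")
})

test_that("select_bandwidth prefers global pooling for constant coefficients", {
  picks <- sapply(1:10, function(s) {
    set.seed(s)
    n <- 60; X <- matrix(rnorm(n * 5), n, 5); m <- rnorm(n)
    y <- X %*% c(1, -0.8, 0.5, 0, 0) + rnorm(n, sd = 0.3)
    cand <- sort(c(0.25, 0.5, 1, 2, 4) * var(m))
    sel <- select_bandwidth(m, cand, X, y, max_anchors = 25)
    match(as.numeric(sel), cand)
  })
  expect_true(all(picks >= 4))       # always in the two largest
  expect_gte(mean(picks == 5), 0.6)  # mostly the largest
})

test_that("select_bandwidth localises for a sharp coefficient switch", {
  below <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 60; X <- matrix(rnorm(n * 5), n, 5); m <- rnorm(n)
    y <- ifelse(m > 0, 1.5, -1.5) * X[, 1] + rnorm(n, sd = 0.3)
    cand <- c(0.25, 0.5, 1, 2, 4) * var(m)
    as.numeric(select_bandwidth(m, cand, X, y, max_anchors = 25)) < max(cand)
  })
  expect_gte(mean(below), 0.8)
})

test_that("select_bandwidth handles trivial candidate lists", {
  expect_identical(select_bandwidth(rnorm(10), 2.5, NULL, NULL), 2.5)
  expect_error(select_bandwidth(rnorm(10), numeric(0), NULL, NULL), "empty")
  expect_error(select_bandwidth(rnorm(10), c(1, -1), NULL, NULL), "positive")
})

test_that("noiseless constant-beta networks are recovered within 0.05", {
  sim <- small_sim(seed = 3, n = 80, J = 6, L = 2, density = 0.5,
                   noise_sd = 0)
  row <- estimate_sample_network(sim$dataset, "drug_A", "TGT001", "S0001",
                                 penalty = penalty_config(lambda = 1e-4),
                                 bandwidth = 4)
  truth <- sim$truth$beta_array["S0001", "TGT001", names(row)]
  expect_lt(max(abs(row - truth)), 0.05)
})

test_that("a target with no true regulators gets an all-zero row at CV lambda", {
  hits <- sapply(1:5, function(s) {
    sim <- small_sim(seed = 100 + s, n = 100, J = 8, L = 4, density = 0.1,
                     noise_sd = 0.5)
    bt <- sim$truth$beta_grid
    empty <- dimnames(bt)[[2]][apply(bt != 0, 2, sum) == 0]
    if (!length(empty)) return(NA)
    row <- estimate_sample_network(
      sim$dataset, "drug_A", empty[1], sim$dataset$sample_ids[1],
      bandwidth = var(sim$dataset$sensitivity[, "drug_A"]))
    all(row == 0)
  })
  hits <- hits[!is.na(hits)]
  expect_gt(length(hits), 0)
  expect_gte(mean(hits), 0.8)
})

test_that("kernel weights concentrate for an extreme anchor", {
  sim <- small_sim(seed = 2, n = 100)
  m <- sim$dataset$sensitivity[, "drug_A"]
  extreme <- names(which.max(m))
  w <- kernel_weights(m, extreme, var(m))$weights
  ess <- sum(w)^2 / sum(w^2)
  expect_lt(ess, length(m) / 2)
})

test_that("estimate_all_networks equals the sequential per-sample loop", {
  sim <- small_sim(seed = 6, n = 5, J = 4, L = 2, density = 0.5)
  pen <- penalty_config(lambda = 0.05)
  stack <- estimate_all_networks(sim$dataset, "drug_A", penalty = pen,
                                 bandwidth = 1)
  expect_identical(dim(stack$coefficients), c(5L, 2L, 4L))
  for (a in sim$dataset$sample_ids) for (tg in sim$dataset$target_ids) {
    row <- estimate_sample_network(sim$dataset, "drug_A", tg, a,
                                   penalty = pen, bandwidth = 1)
    expect_identical(stack$coefficients[a, tg, ], row)
  }
})

test_that("equal modulator values give identical rows; output is deterministic", {
  sim <- small_sim(seed = 8, n = 20, J = 5, L = 2)
  ds <- sim$dataset
  ds$sensitivity[2, "drug_A"] <- ds$sensitivity[1, "drug_A"]
  stack <- estimate_all_networks(ds, "drug_A",
                                 penalty = penalty_config(lambda = 0.02),
                                 bandwidth = 1)
  expect_identical(stack$coefficients[1, , ], stack$coefficients[2, , ])
  stack2 <- estimate_all_networks(ds, "drug_A",
                                  penalty = penalty_config(lambda = 0.02),
                                  bandwidth = 1)
  expect_identical(stack, stack2)
})

test_that("a gene never regulates itself", {
  sim <- small_sim(seed = 9, n = 30, J = 4, L = 2)
  ds <- sim$dataset
  ds$regulator_ids <- c(ds$regulator_ids, "TGT001") # overlap with targets
  row <- estimate_sample_network(ds, "drug_A", "TGT001", ds$sample_ids[1],
                                 penalty = penalty_config(lambda = 0.05),
                                 bandwidth = 1)
  expect_identical(row[["TGT001"]], 0)
})

test_that("stack_edge_list drops exact zeros and round-trips", {
  sim <- small_sim(seed = 6, n = 5, J = 4, L = 2, density = 0.5)
  stack <- estimate_all_networks(sim$dataset, "drug_A",
                                 penalty = penalty_config(lambda = 0.05),
                                 bandwidth = 1)
  el <- stack_edge_list(stack)
  expect_true(all(el$weight != 0))
  expect_identical(nrow(el), sum(stack$coefficients != 0))
})
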
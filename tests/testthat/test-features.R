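test_that("dependency filter selects perfect correlates and honours the fraction", {
  set.seed(1)
  sens <- matrix(rnorm(20), 20, 1, dimnames = list(sprintf("S%02d", 1:20), "d"))
  dep <- matrix(rnorm(300 * 20), 300, 20,
                dimnames = list(sprintf("g%03d", 1:300), rownames(sens)))
  dep["g001", ] <- sens[, 1]        # dependency identical to sensitivity
  dep["g002", ] <- -2 * sens[, 1]   # perfect negative correlate
  sel <- dependency_correlation_filter(dep, sens, "d", top_fraction = 0.01)
  expect_length(sel, 3L) # ceil(0.01 * 300)
  expect_true(all(c("g001", "g002") %in% sel))
  r <- attr(sel, "correlation")
  expect_equal(abs(r[["g001"]]), 1)
})

test_that("dependency filter is invariant to affine sensitivity rescaling", {
  set.seed(2)
  sens <- matrix(rnorm(15), 15, 1, dimnames = list(sprintf("S%02d", 1:15), "d"))
  dep <- matrix(rnorm(50 * 15), 50, 15,
                dimnames = list(sprintf("g%02d", 1:50), rownames(sens)))
  sens2 <- sens * 3.7 + 11
  expect_identical(
    as.character(dependency_correlation_filter(dep, sens, "d", 0.1)),
    as.character(dependency_correlation_filter(dep, sens2, "d", 0.1)))
})

test_that("dependency filter recovers planted genes in simulation", {
  hits <- sapply(1:20, function(s) {
    sim <- small_sim(seed = 400 + s, n = 500, J = 25, L = 5)
    ds <- sim$dataset
    sel <- dependency_correlation_filter(ds$dependency, ds$sensitivity,
                                         "drug_A", top_fraction = 5 / 30)
    all(ds$target_ids %in% sel)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("zero-variance dependency rows warn and score zero", {
  sens <- matrix(1:10, 10, 1, dimnames = list(sprintf("S%02d", 1:10), "d"))
  dep <- rbind(flat = rep(5, 10), live = 1:10)
  colnames(dep) <- rownames(sens)
  expect_warning(sel <- dependency_correlation_filter(dep, sens, "d", 1),
                 "zero-variance")
  expect_identical(sel[1], "live")
})

test_that("regulatory effects match the brute-force triple loop", {
  sim <- small_sim(seed = 10, n = 8, J = 4, L = 3, density = 0.5)
  stack <- estimate_all_networks(sim$dataset, "drug_A",
                                 penalty = penalty_config(lambda = 0.05),
                                 bandwidth = 1)
  tensor <- compute_regulatory_effects(stack, sim$dataset$expression)
  X <- base::scale(t(sim$dataset$expression[stack$regulator_ids, ]))
  for (a in seq_len(8)) for (l in seq_len(3)) for (j in seq_len(4))
    expect_equal(tensor$values[a, l, j],
                 stack$coefficients[a, l, j] * X[a, j])
  # zero coefficients force zero effects
  expect_true(all(tensor$values[stack$coefficients == 0] == 0))
  # raw scale variant
  tensor_raw <- compute_regulatory_effects(stack, sim$dataset$expression,
                                           scale = "raw")
  Xr <- t(sim$dataset$expression[stack$regulator_ids, ])
  expect_equal(tensor_raw$values[3, 2, ],
               stack$coefficients[3, 2, ] * Xr[3, ])
})

test_that("an all-zero stack yields an all-zero tensor; arithmetic is exact", {
  coefs <- array(0, dim = c(2, 1, 2),
                 dimnames = list(c("S1", "S2"), "T1", c("R1", "R2")))
  expr <- matrix(c(3, 1, 4, 1, 5, 9), 3, 2,
                 dimnames = list(c("T1", "R1", "R2"), c("S1", "S2")))
  stack <- make_stack(coefs)
  expect_true(all(compute_regulatory_effects(stack, expr)$values == 0))
  stack$coefficients["S1", "T1", "R1"] <- 2
  t_raw <- compute_regulatory_effects(stack, expr, scale = "raw")
  # regulator R1's expression in S1 is 1, so RE = 2 * 1
  expect_identical(t_raw$values["S1", "T1", "R1"], 2 * expr["R1", "S1"])
})

test_that("compute_regulatory_effects names missing ids", {
  coefs <- array(1, dim = c(2, 1, 1),
                 dimnames = list(c("S1", "S2"), "T1", "R9"))
  expr <- matrix(1, 2, 2, dimnames = list(c("T1", "R1"), c("S1", "S2")))
  expect_error(compute_regulatory_effects(make_stack(coefs), expr), "R9")
})

test_that("compute_regulatory_effects commutes with sample subsetting", {
  sim <- small_sim(seed = 12, n = 10, J = 3, L = 2, density = 0.5)
  stack <- estimate_all_networks(sim$dataset, "drug_A",
                                 penalty = penalty_config(lambda = 0.05),
                                 bandwidth = 1)
  full <- compute_regulatory_effects(stack, sim$dataset$expression,
                                     scale = "raw")
  sub <- stack
  keep <- stack$sample_ids[1:4]
  sub$coefficients <- stack$coefficients[keep, , , drop = FALSE]
  sub$sample_ids <- keep
  part <- compute_regulatory_effects(sub, sim$dataset$expression,
                                     scale = "raw")
  expect_identical(part$values, full$values[keep, , , drop = FALSE])
})

test_that("percentile labelling matches the linear-interpolation convention", {
  sens <- matrix(1:100, 100, 1,
                 dimnames = list(sprintf("S%03d", 1:100), "d"))
  lab <- suppressMessages(label_sensitivity(sens, "d"))
  expect_equal(lab$p_low_value, 10.9)
  expect_equal(lab$p_high_value, 90.1)
  expect_identical(unname(lab$counts["sensitive"]), 10L)
  expect_identical(unname(lab$counts["resistant"]), 10L)
  expect_true(all(lab$labels[1:10] == "sensitive"))
  expect_true(all(lab$labels[91:100] == "resistant"))

  flat <- matrix(5, 12, 1, dimnames = list(sprintf("S%02d", 1:12), "d"))
  lab2 <- suppressMessages(label_sensitivity(flat, "d"))
  expect_true(all(lab2$labels == "intermediate"))
})

test_that("negating sensitivity swaps the sensitive and resistant sets", {
  set.seed(3)
  sens <- matrix(rnorm(40), 40, 1,
                 dimnames = list(sprintf("S%02d", 1:40), "d"))
  a <- suppressMessages(label_sensitivity(sens, "d"))
  b <- suppressMessages(label_sensitivity(-sens, "d"))
  expect_identical(names(which(a$labels == "sensitive")),
                   names(which(b$labels == "resistant")))
  expect_identical(names(which(a$labels == "resistant")),
                   names(which(b$labels == "sensitive")))
})

test_that("class sizes are bounded by the percentile mass", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(20:200, 1)
    sens <- matrix(rnorm(n), n, 1,
                   dimnames = list(sprintf("S%03d", 1:n), "d"))
    lab <- suppressMessages(label_sensitivity(sens, "d"))
    expect_lte(sum(lab$labels == "sensitive"), ceiling(0.1 * n))
    expect_lte(sum(lab$labels == "resistant"), ceiling(0.1 * n))
  }
})

test_that("feature flattening is row-major and invertible", {
  set.seed(4)
  vals <- array(rnorm(6 * 3 * 4), dim = c(6, 3, 4),
                dimnames = list(sprintf("S%02d", 1:6), paste0("T", 1:3),
                                paste0("R", 1:4)))
  tensor <- make_tensor(vals)
  labels <- make_labels(stats::setNames(
    c("sensitive", "resistant", "intermediate", "sensitive", "resistant",
      "sensitive"), sprintf("S%02d", 1:6)))
  fm <- build_feature_matrix(tensor, labels)
  expect_identical(nrow(fm$x), 5L) # intermediate dropped
  expect_identical(ncol(fm$x), 12L)
  expect_identical(unname(fm$y[c("S01", "S02")]), c(1L, 0L))
  # column (l, j) equals the tensor slice for retained samples
  for (l in 1:3) for (j in 1:4) {
    col <- which(fm$column_map$target == paste0("T", l) &
                   fm$column_map$regulator == paste0("R", j))
    expect_identical(unname(fm$x[, col]), unname(vals[rownames(fm$x), l, j]))
  }
  # unflatten(flatten(R_alpha)) = R_alpha
  r1 <- matrix(fm$x["S01", ], nrow = 3, byrow = TRUE,
               dimnames = list(paste0("T", 1:3), paste0("R", 1:4)))
  expect_equal(r1, vals["S01", , ])
})

test_that("build_feature_matrix refuses unclassifiable inputs", {
  vals <- array(1, dim = c(4, 1, 1),
                dimnames = list(paste0("S", 1:4), "T1", "R1"))
  labels <- make_labels(stats::setNames(
    c("sensitive", "resistant", "intermediate", "sensitive"),
    paste0("S", 1:4)))
  expect_error(build_feature_matrix(make_tensor(vals), labels),
               "at least 2 samples")
})
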
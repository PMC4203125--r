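test_that("generators are deterministic given the configuration", {
  cfg <- sim_config(seed = 11, n_genes = 40, tissues = "pulp")
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_physiology(cfg), simulate_physiology(cfg))
})

test_that("noise-free lagged classes trace the common curve shifted in time", {
  cfg <- sim_config(
    seed = 2,
    classes_phys = c("GS", "RS"),
    class_lags_days = c(GS = 10, RS = 0),
    weeks = c(0, 10, 20, 30, 40),
    phys_noise_sd = c(brix = 0, colour = 0, L = 0, C = 0, elasticity = 0)
  )
  phys <- simulate_physiology(cfg)
  means <- tapply(phys$brix, list(phys$class, phys$day), mean)
  # GS at day d equals RS at day d - 10
  expect_equal(unname(means["GS", c("10", "20", "30", "40")]),
               unname(means["RS", c("0", "10", "20", "30")]),
               tolerance = 1e-12)
})

test_that("RS Brix at day 0 equals the configured curve start (12.6)", {
  cfg <- sim_config(seed = 3,
                    phys_noise_sd = c(brix = 0, colour = 0, L = 0, C = 0,
                                      elasticity = 0))
  phys <- simulate_physiology(cfg)
  rs0 <- phys$brix[phys$class == "RS" & phys$day == 0]
  expect_equal(mean(rs0), 12.6, tolerance = 1e-12)
  # and under the default noise the class mean stays within sampling error
  noisy <- phys_default()
  expect_lt(abs(mean(noisy$brix[noisy$class == "RS" & noisy$day == 0]) - 12.6),
            0.2)
})

test_that("non-monotone curve parameters are rejected with a clear message", {
  expect_error(
    sim_config(brix_curve = list(start = 24, asym = 12, rate = 0.03)),
    "not monotone"
  )
  expect_error(
    logistic_curve(0, list(start = 12, asym = 24, rate = -1)),
    "not monotone"
  )
})

test_that("paired designs require at least two replicates", {
  expect_error(simulate_expression(sim_config(seed = 1, n_replicates = 1)),
               "n_replicates")
})

test_that("exact synchronization collapses PostV class means per gene", {
  cfg <- sim_config(seed = 4, n_genes = 30, tissues = "pulp",
                    residual_sd = 0, exact_sync = TRUE)
  sim <- simulate_expression(cfg)
  pv <- sim$meta[sim$meta$stage == "PostV", ]
  mat <- sim$matrix[, pv$sample_id]
  spreads <- apply(mat, 1L, function(x) max(x) - min(x))
  expect_equal(unname(spreads), rep(0, nrow(mat)), tolerance = 1e-12)
  # rv_fold_target = Inf encodes the same degenerate configuration
  cfg2 <- sim_config(seed = 4, n_genes = 30, tissues = "pulp",
                     residual_sd = 0, rv_fold_target = Inf)
  expect_identical(simulate_expression(cfg2)$matrix, sim$matrix)
})

test_that("a null configuration has no between-class structure at veraison", {
  sim <- sim_null()
  var_v <- between_class_variance(sim$matrix, sim$meta, "V", "pulp")
  # class means are pure replicate noise: E[var] = sd^2 / m
  expect_equal(mean(var_v), 0.25^2 / 3, tolerance = 0.1)
  res <- moderated_paired_ttest(sim$matrix, sim$meta, c("GS", "RS"),
                                "pulp", "V")
  expect_lt(sum(res$q < 0.05), 5)
})

test_that("empirical variance-ratio median recovers the fold target", {
  sim <- sim_default()
  var_v <- between_class_variance(sim$matrix, sim$meta, "V", "pulp")
  var_pv <- between_class_variance(sim$matrix, sim$meta, "PostV", "pulp")
  med <- median(rv_score(var_v, var_pv))
  expect_gt(med, 24 * 0.75)
  expect_lt(med, 24 * 1.25)
})

test_that("trend label fractions match the configured mixture", {
  sim <- sim_default()
  n <- nrow(sim$truth)
  p <- 1 / 3
  ci_half <- qnorm(0.995) * sqrt(p * (1 - p) / n)
  for (lab in c("up", "down", "plateau")) {
    expect_lt(abs(mean(sim$truth$trend == lab) - p), ci_half + 1e-12)
  }
})

test_that("the physiology emission is self-consistent with colour_index", {
  phys <- phys_default()
  ci <- colour_index(phys$L, phys$h, phys$C)
  rs0 <- ci[phys$class == "RS" & phys$day == 0]
  expect_lt(abs(mean(rs0) - 3.4), 0.1)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(trend_mix = c(up = 0.5, down = 0.5, plateau = 0.5)),
               "sum to 1")
  expect_error(sim_config(rv_fold_target = 0), "rv_fold_target")
  expect_error(sim_config(class_lags_days = c(GH = 13, GS = 10, PS = 7, RS = 2)),
               "lag 0")
})
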
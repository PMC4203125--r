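test_that("colour_index follows the selected interpretation", {
  expect_equal(colour_index(L = 50, h = 0, C = 10), 0)
  expect_equal(colour_index(L = 40, h = 1, C = 5), 4.0)
  expect_equal(colour_index(L = 40, h = 1, C = 5, formula = "sum"),
               180 / 40 + 5)
  expect_error(colour_index(L = 0, h = 1, C = 0), "undefined")
})

test_that("polynomial ripening fits recover noise-free coefficients exactly", {
  days <- c(0, 7, 14, 21)
  lin <- make_phys(days, "RS", function(d, cl) 10 + 0.5 * d)
  fit1 <- fit_ripening_curve(lin, "RS", "brix", degree = 1)
  expect_equal(fit1$coefficients, c(10, 0.5), tolerance = 1e-9)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-9)

  quad <- make_phys(days, "RS", function(d, cl) 11 + 0.3 * d + 0.01 * d^2)
  fit2 <- fit_ripening_curve(quad, "RS", "brix", degree = 2)
  expect_equal(fit2$coefficients, c(11, 0.3, 0.01), tolerance = 1e-9)
  expect_equal(predict(fit2, 10), 11 + 3 + 1, tolerance = 1e-9)
})

test_that("noisy fits match an independent normal-equations solve", {
  set.seed(21)
  days <- c(0, 7, 14, 21, 35)
  noisy <- make_phys(days, "RS", function(d, cl) 12 + 0.4 * d + rnorm(1, 0, 0.5),
                     n_plants = 4)
  fit <- fit_ripening_curve(noisy, "RS", "brix", window = c(0, 35), degree = 1)
  # brute-force normal equations on the class-day means
  y <- tapply(noisy$brix, noisy$day, mean)
  x <- as.numeric(names(y))
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficients, as.numeric(beta), tolerance = 1e-9)
})

test_that("non-monotone or under-determined fits are rejected", {
  days <- c(0, 7, 14, 21)
  dec <- make_phys(days, "RS", function(d, cl) 20 - 0.2 * d)
  expect_error(fit_ripening_curve(dec, "RS", "brix", degree = 1),
               "not strictly increasing")
  two <- make_phys(c(0, 7), "RS", function(d, cl) 10 + d)
  expect_error(fit_ripening_curve(two, "RS", "brix", degree = 1),
               "insufficient timepoints")
})

test_that("reference stages are the RS class means at 0/7/14/21 d", {
  vals <- c(`0` = 12.6, `7` = 13.9, `14` = 15.3, `21` = 16.4)
  tab <- make_phys(c(0, 7, 14, 21), "RS", function(d, cl) vals[[as.character(d)]])
  st <- define_reference_stages(tab)
  expect_equal(st$id, c("R1", "R2", "R3", "R4"))
  expect_equal(st$brix_ref, unname(vals))
  expect_equal(st$ci_ref, unname(vals) / 3, tolerance = 1e-12)

  flat <- make_phys(c(0, 7, 14, 21), "RS", function(d, cl) 12.6)
  expect_error(define_reference_stages(flat), "strictly increasing")
  expect_error(define_reference_stages(tab[tab$day != 14, ]), "not sampled")
})

test_that("generator reference stages equal the curve values within error", {
  phys <- phys_default()
  cfg <- sim_config(seed = 1)
  st <- define_reference_stages(phys)
  truth <- logistic_curve(c(0, 7, 14, 21), cfg$brix_curve)
  # class-mean SE = noise / sqrt(30 berries)
  se <- 0.25 / sqrt(30)
  expect_true(all(abs(st$brix_ref - truth) < 4 * se))
})

test_that("days_to_reference inverts fitted curves", {
  lin <- make_phys(c(0, 7, 14, 21), "RS", function(d, cl) 10 + 0.5 * d)
  fit <- fit_ripening_curve(lin, "RS", "brix", degree = 1)
  expect_equal(days_to_reference(fit, 12.6), 5.2, tolerance = 1e-6)

  quad <- make_phys(c(0, 7, 14, 21), "RS",
                    function(d, cl) 11 + 0.3 * d + 0.01 * d^2)
  fitq <- fit_ripening_curve(quad, "RS", "brix", degree = 2)
  for (ref in c(12, 14, 16, 18)) {
    day <- days_to_reference(fitq, ref)
    # brute-force grid search at 1e-4 d resolution
    grid <- seq(0, 35, by = 1e-4)
    gday <- grid[which.min(abs(poly_eval_test(fitq$coefficients, grid) - ref))]
    expect_lt(abs(day - gday), 1e-4 + 1e-8)
    # composing with the fit is the identity
    expect_equal(predict(fitq, day), ref, tolerance = 1e-5)
  }
  expect_error(days_to_reference(fitq, 100), "unreachable")
  expect_error(days_to_reference(fitq, 5), "below the fitted range")
})

test_that("lagged synthetic classes recover their generating shifts", {
  phys <- phys_default()
  st <- define_reference_stages(phys)
  lags <- c(PS = 7, GS = 10, GH = 13)
  for (cl in names(lags)) {
    fit <- fit_ripening_curve(phys, cl, "brix")
    day <- days_to_reference(fit, st$brix_ref[st$id == "R1"])
    expect_lt(abs(day - lags[[cl]]), 0.5)
  }
})

test_that("lag tables round half-up and subtract the reference day", {
  r1 <- data.frame(class = c("RS", "PS", "GS", "GH"), stage = "R1",
                   day = c(0, 6.5, 9.9, 13.0))
  lt1 <- lag_table(r1, c(R1 = 0))
  expect_equal(lt1$rounded_lag, c(0, 7, 10, 13))
  expect_equal(lt1$lag_vs_rs, c(0, 6.5, 9.9, 13.0))

  r3 <- data.frame(class = c("RS", "PS", "GS", "GH"), stage = "R3",
                   day = c(14, 15.4, 17.0, 19.1))
  expect_equal(lag_table(r3, c(R3 = 14))$rounded_lag, c(0, 1, 3, 5))

  same <- data.frame(class = c("A", "B"), stage = "R1", day = c(3, 3))
  expect_equal(lag_table(same, c(R1 = 3))$lag_vs_rs, c(0, 0))
  expect_error(lag_table(r1, c(R2 = 0)), "missing reference day")
})

test_that("accumulation rates are reference deltas over day deltas", {
  stages <- data.frame(id = c("R1", "R2", "R3"), rs_day = c(0, 7, 14),
                       brix_ref = c(12.6, 13.9, 15.3),
                       ci_ref = c(3.4, 4.4, 5.1))
  days <- data.frame(class = "RS", stage = c("R1", "R2", "R3"),
                     day = c(0, 7, 14))
  rt <- accumulation_rates(stages, days, "brix")
  expect_equal(rt$rate[rt$interval == "R1->R2"], (13.9 - 12.6) / 7)

  # linear trajectory: every interval rate equals the slope
  r <- 0.25
  days2 <- data.frame(class = "PS", stage = c("R1", "R2", "R3"),
                      day = c(12.6, 13.9, 15.3) / r)
  rt2 <- accumulation_rates(stages, days2, "brix")
  expect_equal(rt2$rate, rep(r, 2), tolerance = 1e-12)

  # smaller day span for the same reference delta -> larger rate
  fast <- data.frame(class = "GS", stage = c("R1", "R2"), day = c(0, 3.5))
  slow <- data.frame(class = "GH", stage = c("R1", "R2"), day = c(0, 7))
  expect_gt(accumulation_rates(stages, fast, "brix")$rate,
            accumulation_rates(stages, slow, "brix")$rate)
  expect_error(accumulation_rates(
    stages, data.frame(class = "X", stage = c("R1", "R2"), day = c(7, 7)),
    "brix"
  ), "strictly increasing")

  # rates are invariant to shifting all days by a constant
  rt3 <- accumulation_rates(stages, transform(days2, day = day + 11), "brix")
  expect_equal(rt3$rate, rt2$rate, tolerance = 1e-12)
})

test_that("rate comparison assigns Tukey letters sensibly", {
  set.seed(31)
  base <- rnorm(5, 1, 0.1)
  same <- data.frame(class = rep(c("A", "B", "C"), each = 5),
                     plant = rep(1:5, 3), rate = rep(base, 3))
  cs <- compare_rates(same)
  expect_equal(length(unique(cs$letters)), 1L)

  apart <- data.frame(class = rep(c("A", "B"), each = 5), plant = rep(1:5, 2),
                      rate = c(rnorm(5, 0, 0.05), rnorm(5, 0.5, 0.05)))
  ca <- compare_rates(apart)
  expect_false(grepl(ca$letters[["A"]], ca$letters[["B"]], fixed = TRUE))
  expect_lt(ca$anova_p, 0.001)

  degen <- data.frame(class = rep(c("A", "B"), each = 3), plant = rep(1:3, 2),
                      rate = rep(c(1, 2), each = 3))
  cd <- suppressWarnings(compare_rates(degen))
  expect_true(cd$degenerate)
  expect_false(grepl(cd$letters[["A"]], cd$letters[["B"]], fixed = TRUE))
})

test_that("equivalent-stage ratios behave like ratios", {
  expect_equal(equivalent_stage_ratio(c(R1 = 2), c(R1 = 2)), c(R1 = 1))
  expect_equal(unname(equivalent_stage_ratio(0.7 * c(5, 3), c(5, 3))),
               c(0.7, 0.7))
  gs <- c(1.2, 0.4)
  rs <- c(0.9, 1.7)
  expect_equal(equivalent_stage_ratio(gs, rs) * equivalent_stage_ratio(rs, gs),
               rep(1, 2), tolerance = 1e-12)
  expect_error(equivalent_stage_ratio(1, 0), "> 0")
})

test_that("between-class spread is the range of class means", {
  tab <- make_phys(0, c("A", "B", "C"),
                   function(d, cl) c(A = 10, B = 12, C = 15)[[cl]])
  expect_equal(between_class_spread(tab, 0, "brix"), 5)
  flat <- make_phys(0, c("A", "B"), function(d, cl) 10)
  expect_equal(between_class_spread(flat, 0, "brix"), 0)
  expect_error(between_class_spread(tab, 99, "brix"), "no measurements")

  # lagged classes converge: spread shrinks across the sampled window
  phys <- phys_default()
  spreads <- vapply(c(0, 21, 42), function(d) {
    between_class_spread(phys, d, "brix")
  }, numeric(1))
  expect_true(all(diff(spreads) < 0))
})
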
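test_that("the annuity factor matches term-by-term summation", {
  expect_equal(annuity_factor(0, 10), 10)
  expect_equal(annuity_factor(0.035, 1), 1)
  # oracle: direct summation of discount weights, first period undiscounted
  oracle <- sum(1.035^-(0:9))
  expect_equal(annuity_factor(0.035, 10), oracle, tolerance = 1e-12)
  expect_equal(annuity_factor(0.035, 10), 8.60769, tolerance = 1e-5 / 8.6)
  rates <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(sapply(rates, annuity_factor, years = 10)) < 0))
})

test_that("potential improvement is the gap to target, floored at zero", {
  expect_equal(potential_improvement(0.345, 0.745), 0.4)
  expect_equal(potential_improvement(0.745, 0.745), 0)
  expect_equal(potential_improvement(0.90, 0.745), 0)
})

test_that("per-person QALYs follow the closed-form trajectory arithmetic", {
  cfg <- sim_config()
  A <- sum(1.035^-(0:9))
  S <- sum((0:9) * 1.035^-(0:9))
  # control arm: u0 * A - d * S while no clamping binds
  expect_equal(person_qalys(0.3386, "control", cfg), 0.3386 * A - 0.005 * S,
               tolerance = 1e-12)
  expect_equal(person_qalys(0.3386, "control", cfg), 2.733, tolerance = 0.001 / 2.733)
  # treatment effect: delta * (ramp half-year + full years), discounted
  gain <- person_qalys(0.345, "treatment", cfg) - person_qalys(0.345, "control", cfg)
  expect_equal(gain, 0.3 * (0.5 + A - 1), tolerance = 1e-12)
  expect_equal(gain, 2.432, tolerance = 0.001 / 2.432)
  # a patient at the target gains nothing
  expect_equal(person_qalys(0.745, "treatment", cfg),
               person_qalys(0.745, "control", cfg))
  expect_error(person_qalys(0.5, "placebo", cfg))
  expect_error(person_qalys(1.2, "control", cfg), "bounds")
})

test_that("trajectories are clamped at the value-set floor", {
  cfg <- sim_config()
  floor <- cfg$utility_bounds[1]
  # a patient at the floor cannot decline further: control QALYs = floor * annuity
  expect_equal(person_qalys(floor, "control", cfg),
               floor * annuity_factor(0.035, 10), tolerance = 1e-12)
})

test_that("the simulation reproduces the published totals for the anchor utility", {
  res <- simulate_cua(rep(0.3386, 15))
  expect_equal(res$aggregate$total_untreated, 41, tolerance = 0.001)
  expect_equal(res$aggregate$mean_gain, 2.47, tolerance = 0.002)
  expect_equal(res$aggregate$total_treated,
               res$aggregate$total_untreated + 15 * res$aggregate$mean_gain)
  # conservation: aggregates are sums of per-person QALYs
  expect_equal(res$aggregate$total_treated, sum(res$per_person$qalys_treated))
  expect_equal(res$aggregate$interval95,
               res$aggregate$mean_gain + c(-1.96, 1.96) * res$aggregate$sd_gain)
  expect_error(simulate_cua(numeric(0)), "empty")
})

test_that("gain shrinks to zero with the attainment fraction", {
  cfg <- sim_config(attainment = 1e-9)
  res <- simulate_cua(0.4, cfg)
  expect_lt(res$aggregate$mean_gain, 1e-8)
})

test_that("gain is invariant to the ageing decrement when clamping does not bind", {
  u0 <- c(0.2, 0.35, 0.5, 0.7)
  g_with <- simulate_cua(u0, sim_config())$aggregate$mean_gain
  g_without <- simulate_cua(u0, sim_config(aging_decrement = 0))$aggregate$mean_gain
  expect_equal(g_with, g_without, tolerance = 1e-12)
})

test_that("gain is exactly linear in attainment absent clamping", {
  u0 <- c(0.2, 0.35, 0.5)
  sens <- sensitivity_gains(u0, sim_config(), grid = c(0.55, 0.75, 0.95))
  expect_equal(sens$mean_gain[1] / sens$mean_gain[2], 55 / 75, tolerance = 1e-12)
  expect_equal(sens$mean_gain[3] / sens$mean_gain[2], 95 / 75, tolerance = 1e-12)
  # closed form at full attainment: gap 0.1 for everyone
  g <- sensitivity_gains(rep(0.645, 4), sim_config(), grid = 1)$mean_gain
  expect_equal(g, 0.1 * (0.5 + sum(1.035^-(0:9)) - 1), tolerance = 1e-12)
})

test_that("willingness-to-pay satisfies the ICER identity and Table anchors", {
  cfg <- sim_config()
  expect_equal(round(wtp_annual(50000, 2.4712, cfg)), 14355)
  expect_equal(round(wtp_annual(20000, 2.4712, cfg)), 5742)
  expect_equal(wtp_annual(0, 2.4712, cfg), 0)
  # discounted payment stream equals threshold x gain
  annual <- wtp_annual(50000, 2.4712, cfg)
  expect_equal(annual * annuity_factor(cfg$discount_rate, cfg$horizon_years),
               50000 * 2.4712, tolerance = 1e-9)
})

test_that("the WTP table is linear in threshold and proportional to gain", {
  gains <- data.frame(attainment = c(0.55, 0.75, 0.95),
                      mean_gain = c(1.812, 2.4712, 3.130))
  w <- build_wtp_table(gains)
  expect_equal(dim(unclass(w)), c(9, 3))
  expect_equal(unclass(w)["40000", ] / unclass(w)["20000", ], rep(2, 3),
               ignore_attr = TRUE)
  expect_equal(unclass(w)["50000", "75%"] / unclass(w)["20000", "75%"], 2.5,
               tolerance = 1e-12)
  one <- build_wtp_table(c(base = 2.4712), thresholds = 50000)
  expect_equal(as.numeric(one), wtp_annual(50000, 2.4712))
  expect_error(build_wtp_table(c(base = 0)), "positive")
})

test_that("the empirical middle-tertile helper reproduces the target-setting rule", {
  d <- data.frame(id = sprintf("p%02d", 1:9), utility = seq(0.1, 0.9, by = 0.1))
  expect_equal(middle_tertile_target(d), mean(c(0.4, 0.5, 0.6)))
})
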
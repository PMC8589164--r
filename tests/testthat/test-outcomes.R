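test_that("discount factors follow the annual rate at quarterly cycles", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(4, 0.03), 1 / 1.03)
  expect_equal(discount_factor(4, 0.03), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(40, 0.03), 1.03^-10)
  expect_equal(discount_factor(40, 0.03), 0.744094, tolerance = 1e-6)
  expect_equal(discount_factor(10, 0), 1)
})

test_that("baseline utility evaluates the published quadratic", {
  co <- test_config$baseline_utility_coeffs
  expect_equal(round(baseline_utility(69.9, 0.71, co), 3), 0.805)
  expect_equal(baseline_utility(69.9, 0.71, co), 0.8045848,
               tolerance = 1e-7)
  expect_equal(baseline_utility(0, 0, co), 0.9454933)
  expect_equal(baseline_utility(50, 1, co), 0.886575, tolerance = 1e-6)
  ages <- seq(60, 100, by = 5)
  expect_true(all(diff(baseline_utility(ages, 0.71, co)) < 0))
})

test_that("state utilities multiply acute and post-acute ratios", {
  cfg <- test_config
  expect_equal(state_utility("event_free|on", 0, cfg), 0.8045848,
               tolerance = 1e-6)
  expect_equal(state_utility("dead", 0, cfg), 0)
  expect_equal(state_utility("MI:post|on", 0, cfg), 0.8045848 * 0.878,
               tolerance = 1e-6)
  expect_equal(state_utility("MI:post|on", 0, cfg), 0.70644,
               tolerance = 1e-4)
  # joint post-acute state multiplies both ratios
  expect_equal(state_utility("MI+IS:post|off", 0, cfg),
               0.8045848 * 0.878 * 0.825, tolerance = 1e-6)
  # acute state: acute ratio of the incident event x post-acute ratio of
  # the other history event
  expect_equal(state_utility("MI+IS:acute_IS|on", 0, cfg),
               0.8045848 * 0.771 * 0.878, tolerance = 1e-6)
  # short-term intensities scale multiplicatively
  u0 <- state_utility("event_free|on", 0, cfg)
  u1 <- state_utility("event_free|on", 0, cfg,
                      short_term_intensities = c(0.5, 0, 0))
  expect_equal(u1 / u0, 1 - 0.5 * (1 - 0.988), tolerance = 1e-12)
})

test_that("life years reduce to the discounted annuity without mortality", {
  cfg <- zero_config()
  horizon <- 40
  res <- summarize_arm(run_trace(cfg, "apixaban", horizon = horizon), cfg)
  annuity <- sum(0.25 * 1.03^(-0.25 * (0:(horizon - 1))))
  expect_equal(res$total_ly, annuity, tolerance = 1e-9)
  cfg0 <- cfg
  cfg0$run$discount_rate_annual <- 0
  res0 <- summarize_arm(run_trace(cfg0, "apixaban", horizon = horizon),
                        cfg0)
  expect_equal(res0$total_ly, 10)
})

test_that("zero-discount totals dominate discounted totals component-wise", {
  cfg <- test_config
  cfg0 <- cfg
  cfg0$run$discount_rate_annual <- 0
  res <- summarize_arm(run_trace(cfg, "vka", horizon = 40), cfg)
  res0 <- summarize_arm(run_trace(cfg0, "vka", horizon = 40), cfg0)
  expect_true(all(res0$costs >= res$costs))
  expect_gte(res0$total_ly, res$total_ly)
  expect_gte(res0$total_qaly, res$total_qaly)
})

test_that("QALYs never exceed LYs and components are non-negative", {
  for (arm in c("apixaban", "vka")) {
    res <- summarize_arm(run_trace(test_config, arm), test_config)
    expect_lte(res$total_qaly, res$total_ly)
    expect_true(all(res$costs >= 0))
    expect_equal(res$total_cost_payer,
                 sum(res$costs[c("treatment", "monitoring", "acute_direct",
                                 "maintenance_direct")]))
    expect_equal(res$total_cost_societal,
                 res$total_cost_payer + sum(res$costs[c(
                   "acute_indirect", "maintenance_indirect")]))
    expect_equal(res$time_on_treatment + res$time_off_treatment,
                 res$total_ly, tolerance = 1e-9)
  }
})

test_that("societal totals equal payer totals when indirect rows are zeroed", {
  cfg <- test_config
  cfg$event_costs$societal_acute <- 0
  cfg$event_costs$societal_monthly <- 0
  res <- summarize_arm(run_trace(cfg, "apixaban", horizon = 20), cfg)
  expect_equal(res$total_cost_societal, res$total_cost_payer)
})

test_that("incremental measures follow their definitions", {
  arm <- function(cost, qaly, ly = qaly) {
    structure(list(total_cost_payer = cost, total_cost_societal = cost,
                   total_ly = ly, total_qaly = qaly,
                   events_per_100 = stats::setNames(rep(0, 7), c(
                     "OMB", "MI", "IS", "ICH", "CRNMB", "REV", "SE"))),
              class = "arm_results")
  }
  inc <- incremental(arm(1000, 1.1), arm(2000, 1.0), wtp = 20000)
  expect_equal(inc$delta_cost, -1000)
  expect_equal(inc$inmb, 20000 * 0.1 + 1000)
  expect_equal(inc$inmb, 3000)
  expect_equal(inc$inhb, 0.15)
  expect_equal(inc$dominance, "dominant")
  inc <- incremental(arm(3000, 1.1), arm(2000, 1.0), wtp = 20000)
  expect_equal(inc$icer, 10000)
  expect_equal(inc$dominance, "cost_effective")
  inc <- incremental(arm(9000, 1.1), arm(2000, 1.0), wtp = 20000)
  expect_equal(inc$dominance, "not_cost_effective")
  inc <- incremental(arm(3000, 0.9), arm(2000, 1.0), wtp = 20000)
  expect_equal(inc$dominance, "dominated")
  # INHB = INMB / WTP by construction
  expect_equal(inc$inhb, inc$inmb / 20000)
})

test_that("per-cycle cost components respect the off-treatment rule", {
  cfg <- test_config
  tr <- run_trace(cfg, "apixaban", horizon = 12)
  comp <- cycle_costs(tr, 4, cfg, "payer")
  expect_true(all(comp >= 0))
  expect_named(comp, c("treatment", "monitoring", "acute", "maintenance"))
  soc <- cycle_costs(tr, 4, cfg, "societal")
  expect_true(all(c("indirect_acute", "indirect_maintenance") %in%
                    names(soc)))
  expect_error(cycle_costs(tr, 4, cfg, "insurer"), "perspective")
  # apixaban arm never accrues monitoring cost
  expect_equal(unname(comp["monitoring"]), 0)
})
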
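test_that("the shipped pack loads with published values in place", {
  cfg <- test_config
  r <- event_rates(cfg, "triple_or_dual", "apixaban")
  expect_equal(unname(r["OMB"]), 6.25)
  expect_equal(unname(r["SE"]), 0.09)
  r <- event_rates(cfg, "mono", "vka")
  expect_equal(unname(r["ICH"]), 0.73)
  expect_equal(unname(cfg$mortality_hr["IS"]), 2.60)
  expect_equal(cfg$subsequent_hr["ICH", "IS"], 1.78)
  expect_equal(horizon_cycles(cfg), 121)
})

test_that("validation rejects broken packs with named errors", {
  cfg <- test_config
  bad <- cfg
  bad$p2y12$clopidogrel[1] <- 0.5
  bad$p2y12$prasugrel[1] <- 0.5
  bad$p2y12$ticagrelor[1] <- 0.5
  expect_error(validate_model_config(bad), "p2y12")

  bad <- cfg
  bad$fatality$cfr[1] <- 1.2
  expect_error(validate_model_config(bad), "cfr")

  bad <- cfg
  bad$rates$rate[3] <- -1
  expect_error(validate_model_config(bad), "rate")

  bad <- cfg
  bad$run$cycle_days <- 90
  expect_error(validate_model_config(bad), "cycle_days")

  bad <- cfg
  bad$subsequent_hr["MI", "IS"] <- 1.5
  expect_error(validate_model_config(bad), "prior-MI")
})

test_that("per-cycle drug costs are consistent with full-precision prices", {
  cfg <- test_config
  cycle_days <- cfg$run$cycle_days
  expect_equal(cycle_days, 365.25 / 4)
  for (agent in c("apixaban", "acenocoumarol", "prasugrel")) {
    i <- match(agent, cfg$drugs$agent)
    computed <- cfg$drugs$price_per_mg[i] * cfg$drugs$daily_dose_mg[i] *
      cycle_days
    expect_equal(round(computed, 2), round(cfg$drugs$cost_per_cycle[i], 2),
                 info = agent)
  }
  expect_equal(drug_cost_per_cycle(cfg, "apixaban"), 173.49)
  expect_equal(drug_cost_per_cycle(cfg, "acenocoumarol"), 13.70)
})

test_that("off-treatment rates invert the apixaban-vs-no-treatment HRs", {
  cfg <- test_config
  off <- event_rates(cfg, "off", "apixaban")
  expect_equal(unname(off["IS"]), 0.97 / 0.26, tolerance = 1e-12)
  expect_equal(unname(off["IS"]), 3.7308, tolerance = 1e-4)
  expect_equal(unname(off["OMB"]), 2.12 / 1.24, tolerance = 1e-12)
  expect_equal(unname(off["OMB"]), 1.7097, tolerance = 1e-4)
  # same off rates in both arms
  expect_identical(off, event_rates(cfg, "off", "vka"))
  # HR of 1 leaves the rate unchanged, and the derivation inverts
  # multiplication by the HR exactly
  mono <- event_rates(cfg, "mono", "apixaban")
  hr1 <- stats::setNames(rep(1, 7), names(mono))
  expect_equal(derive_no_treatment_rates(mono, hr1), mono)
  expect_equal(off * cfg$no_treatment_hr[names(off)], mono)
  expect_error(derive_no_treatment_rates(mono, hr1 * 0), "> 0")
})

test_that("weighted P2Y12 cost matches the share-weighted sum", {
  cfg <- test_config
  costs <- stats::setNames(cfg$drugs$cost_per_cycle, cfg$drugs$agent)
  apix <- c(clopidogrel = 0.934, prasugrel = 0.012, ticagrelor = 0.054)
  expect_equal(weighted_p2y12_cost(apix, costs), 62.4887, tolerance = 1e-4)
  vka <- c(clopidogrel = 0.918, prasugrel = 0.011, ticagrelor = 0.071)
  expect_equal(weighted_p2y12_cost(vka, costs), 64.8594, tolerance = 1e-4)
  expect_equal(weighted_p2y12_cost(
    c(clopidogrel = 1, prasugrel = 0, ticagrelor = 0), costs), 54.82)
  expect_error(weighted_p2y12_cost(
    c(clopidogrel = 0.5, prasugrel = 0.5, ticagrelor = 0.5), costs),
    "sum to 1")
})

test_that("a model configuration round-trips through serialization", {
  cfg <- test_config
  path <- tempfile(fileext = ".json")
  write_model_config(cfg, path)
  back <- read_model_config(path)
  expect_equal(back$rates, cfg$rates, tolerance = 1e-12)
  expect_equal(back$subsequent_hr, cfg$subsequent_hr, tolerance = 1e-12)
  expect_equal(back$no_treatment_hr, cfg$no_treatment_hr,
               tolerance = 1e-12)
  expect_equal(back$cohort, cfg$cohort, tolerance = 1e-12)
  expect_equal(back$baseline_utility_coeffs, cfg$baseline_utility_coeffs,
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$life_table),
               as.data.frame(cfg$life_table), tolerance = 1e-12)
  expect_equal(back$fatality$age_hi, cfg$fatality$age_hi)
  # a re-loaded config produces the identical base case
  expect_equal(run_base_case(back)$incremental_payer$delta_cost,
               run_base_case(cfg)$incremental_payer$delta_cost,
               tolerance = 1e-10)
  unlink(path)
})
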
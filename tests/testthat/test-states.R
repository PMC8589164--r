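test_that("the state space enumerates 55 states with the expected shapes", {
  st <- enumerate_states()
  expect_equal(nrow(st), 55)
  alive <- st[st$phase != "dead", ]
  expect_equal(sum(st$phase == "dead"), 1)
  for (tx in c("on", "off")) {
    s <- alive[alive$tx == tx, ]
    expect_equal(nrow(s), 27)
    expect_equal(sum(s$phase == "event_free"), 1)
    single <- s[!grepl("+", s$history, fixed = TRUE) & nzchar(s$history), ]
    expect_equal(sum(single$phase == "acute"), 4)
    expect_equal(sum(single$phase == "post_acute"), 4)
    pairs <- s[grepl("+", s$history, fixed = TRUE), ]
    expect_equal(sum(pairs$phase == "acute"), 12)
    expect_equal(sum(pairs$phase == "post_acute"), 6)
  }
  # acute event always belongs to the history
  acute <- st[st$phase == "acute", ]
  expect_true(all(mapply(grepl, acute$acute_event, acute$history,
                         MoreArgs = list(fixed = TRUE))))
})

test_that("recurrent events map back to the existing acute state", {
  cfg <- test_config
  sched <- build_schedule(scenario_spec(), 10)
  st <- enumerate_states()
  # from post-acute IS (on), a recurrent IS lands in the acute IS state
  # with the same singleton history
  row <- build_transition_row("IS:post|on", 3, sched, cfg)
  expect_gt(row[["IS:acute_IS|on"]], 0)
  # from a two-event history only those events can recur
  row <- build_transition_row("IS+ICH:post|on", 3, sched, cfg)
  landing <- names(row)[row > 0]
  acute_dest <- grep("acute", landing, value = TRUE)
  expect_setequal(acute_dest, c("IS+ICH:acute_IS|on", "IS+ICH:acute_ICH|on",
                                "IS+ICH:acute_IS|off",
                                "IS+ICH:acute_ICH|off"))
  expect_true(all(st$name[st$phase == "acute"] %in% st$name))
})

test_that("aging multiplier follows the per-decade HR after month 6", {
  hr <- test_config$aging_hr
  expect_equal(aging_multiplier("OMB", 80.4, 70.4, hr), 1.97)
  expect_equal(aging_multiplier("OMB", 70.4, 70.4, hr), 1)
  expect_equal(aging_multiplier("MI", 69.9, 70.4, hr), 1)
  expect_equal(aging_multiplier("OMB", 75.4, 70.4, hr), 1.97^0.5)
  expect_equal(aging_multiplier("OMB", 75.4, 70.4, hr), 1.40357,
               tolerance = 1e-5)
  expect_equal(aging_multiplier("CRNMB", 90, 70.4, hr), 1)  # not aged
})

test_that("history multipliers multiply subsequent-event HRs", {
  hr <- test_config$subsequent_hr
  expect_equal(history_multiplier("ICH", "IS", hr), 1.78)
  expect_equal(history_multiplier("MI", "MI", hr), 1.00)
  expect_equal(history_multiplier("MI", "IS", hr), 1.00)
  expect_equal(history_multiplier(character(0), "IS", hr), 1)
  expect_equal(history_multiplier(c("IS", "ICH"), "IS", hr), 4.00 * 1.78)
  expect_equal(history_multiplier(c("IS", "ICH"), "IS", hr), 7.12,
               tolerance = 1e-12)
  expect_error(history_multiplier(c("IS", "ICH"), "MI", hr),
               "not permitted")
})

test_that("event fatality uses age bands with clamping below", {
  ft <- test_config$fatality
  expect_equal(event_fatality("IS", 70, ft), 0.109)
  expect_equal(event_fatality("ICH", 80, ft), 0.268)
  expect_equal(event_fatality("MI", 55, ft), 0.071)   # clamp to 60-70
  expect_equal(event_fatality("MI", 95, ft), 0.316)
  expect_equal(event_fatality("OMB", 40, ft), 0.02)
  expect_equal(event_fatality("OMB", 99, ft), 0.02)
})

test_that("background death pro-rates the annual probability on the hazard scale", {
  expect_equal(background_death_prob(0.02, 2.6), 1 - 0.98^0.65)
  expect_equal(background_death_prob(0.02, 2.6), 0.0130447,
               tolerance = 1e-4)
  expect_equal(background_death_prob(0, 5), 0)
  expect_equal(background_death_prob(0.02, 1), 0.0050378,
               tolerance = 1e-4)
  expect_equal(background_death_prob(1, 1), 1)
  expect_error(background_death_prob(0.02, 0), "> 0")
})

test_that("competing-risk conversion matches the closed form", {
  one <- rate_to_competing_probs(c(OMB = 6.25), 0.25)
  expect_equal(unname(one$p["OMB"]), 1 - exp(-0.015625))
  expect_equal(unname(one$p["OMB"]), 0.0155036, tolerance = 1e-5)
  two <- rate_to_competing_probs(c(a = 4, b = 4), 0.25)
  expect_equal(unname(two$p), rep(0.5 * (1 - exp(-0.02)), 2))
  expect_equal(unname(two$p), rep(0.0099007, 2), tolerance = 1e-5)
  expect_equal(sum(two$p) + two$stay, 1)
  none <- rate_to_competing_probs(c(a = 0, b = 0), 0.25)
  expect_equal(none$stay, 1)
  expect_error(rate_to_competing_probs(c(a = -1)), "non-negative")
})
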
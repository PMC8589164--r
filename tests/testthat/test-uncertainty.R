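test_that("one-way bounds use CI, then 1.96 SE, then +/- 10%", {
  cfg <- test_config
  b <- dsa_bounds("hr_aging|OMB", cfg)
  expect_equal(c(b$low, b$high), c(1.79, 2.16))
  expect_equal(b$source, "ci")
  b <- dsa_bounds("cost_drug|apixaban", cfg)
  expect_equal(c(b$low, b$high), c(156.141, 190.839), tolerance = 1e-6)
  expect_equal(b$source, "pct10")
  b <- dsa_bounds("disc_event|ICH", cfg)
  expect_equal(c(b$low, b$high), c(0.558 - 1.96 * 0.0689,
                                   0.558 + 1.96 * 0.0689))
  expect_equal(round(c(b$low, b$high), 4), c(0.4230, 0.6930))
  expect_equal(b$source, "se")
  expect_error(dsa_bounds("no_such_parameter", cfg), "unknown")
})

test_that("the registry covers every varied block and respects bounds", {
  reg <- psa_registry(test_config)
  expect_true(all(reg$low <= reg$mean + 1e-12))
  expect_true(all(reg$mean <= reg$high + 1e-12))
  prefixes <- unique(sub("\\|.*", "", reg$id))
  expect_true(all(c("rate", "hr_no_treatment", "hr_aging",
                    "hr_subsequent", "hr_mortality", "cfr", "disc_event",
                    "disc_unrelated", "cost_drug", "cost_acute",
                    "cost_maint", "cost_inr", "util_acute", "util_post",
                    "age", "male_share") %in% prefixes))
  expect_equal(sum(prefixes == "rate"), 1)
  expect_equal(sum(reg$dist == "gamma" & grepl("^rate", reg$id)), 56)
})

test_that("a parameter with no effect on the base case has zero swing", {
  # warfarin's unit cost is unused under the acenocoumarol base case
  d <- run_dsa(test_config, parameters = "cost_drug|warfarin")
  expect_equal(d$swing, 0)
  expect_equal(d$inmb_low, d$inmb_high)
})

test_that("setting a parameter to its base value reproduces the base INMB", {
  cfg <- test_config
  base <- run_base_case(cfg)
  inmb0 <- base$incremental_payer$inmb
  for (id in c("hr_aging|OMB", "cost_acute|IS", "disc_unrelated|vka")) {
    b <- dsa_bounds(id, cfg)
    cfg2 <- oaccea:::config_set(cfg, id, b$base)
    res <- run_base_case(cfg2)
    expect_equal(res$incremental_payer$inmb, inmb0, tolerance = 1e-12,
                 info = id)
  }
})

test_that("swapping a parameter's bounds mirrors the swing", {
  d <- run_dsa(test_config, parameters = "cost_drug|apixaban")
  # INMB at the low apixaban price must exceed INMB at the high price
  expect_gt(d$inmb_low, d$inmb_high)
  expect_equal(d$swing, abs(d$inmb_high - d$inmb_low))
})

test_that("sampling distributions recover their mean and SE", {
  set.seed(99)
  n <- 10000
  # gamma, moment-matched to an event rate
  x <- replicate(n, oaccea:::sample_one("gamma", 6.25, 0.02, NA, NA))
  expect_equal(mean(x), 6.25, tolerance = 3 * 0.02 / sqrt(n) / 6.25 + 1e-4)
  expect_equal(stats::sd(x), 0.02, tolerance = 0.05)
  # beta, moment-matched to a probability (alpha 74.75, beta 224.25)
  x <- replicate(n, oaccea:::sample_one("beta", 0.25, 0.025, NA, NA))
  expect_equal(mean(x), 0.25, tolerance = 3 * 0.025 / sqrt(n) / 0.25)
  expect_equal(stats::sd(x), 0.025, tolerance = 0.05)
  # lognormal: sigma from the CI on the log scale
  x <- replicate(n, oaccea:::sample_one("lognormal", 0.26, NA, 0.18, 0.37))
  expect_equal(stats::sd(log(x)), (log(0.37) - log(0.18)) / 3.92,
               tolerance = 0.05)
  expect_equal(stats::sd(log(x)), 0.18381, tolerance = 0.01)
  expect_equal(stats::median(x), 0.26, tolerance = 0.01)
  # degenerate: zero SE returns the mean
  expect_equal(oaccea:::sample_one("gamma", 5, 0, NA, NA), 5)
  # truncated normal respects its bounds
  x <- replicate(200, oaccea:::sample_one("normal", 69.9, 10, NA, NA,
                                          trunc = c(60, 75)))
  expect_true(all(x >= 60 & x <= 75))
})

test_that("every PSA draw passes full validation and is reproducible", {
  cfg <- test_config
  set.seed(7)
  for (i in 1:10) {
    d <- draw_psa_config(cfg)
    expect_s3_class(d$config, "model_config")  # validated on construction
    shares <- unlist(d$config$p2y12[1, -1])
    expect_equal(sum(shares), 1, tolerance = 1e-9)
  }
  p1 <- run_psa(cfg, n = 4, seed = 42)
  p2 <- run_psa(cfg, n = 4, seed = 42)
  expect_identical(p1$draws, p2$draws)
})

test_that("CEAC limits and tie handling follow the definition", {
  draws <- data.frame(delta_cost = c(-100, -50, 200, 300),
                      delta_qaly = c(0.1, 0.2, 0.01, -0.05))
  fake <- structure(list(draws = draws, wtp = 20000), class = "psa_results")
  cc <- ceac(fake, wtp_grid = c(0, 1e9))
  expect_equal(cc$probability[1], mean(draws$delta_cost < 0))
  expect_equal(cc$probability[2], mean(draws$delta_qaly > 0))
  # all-dominant draws give a curve identically 1
  dom <- structure(list(draws = data.frame(delta_cost = c(-1, -2),
                                           delta_qaly = c(0.1, 0.2)),
                        wtp = 20000), class = "psa_results")
  expect_true(all(ceac(dom, c(0, 20000, 50000))$probability == 1))
  # a zero-NMB draw counts one half
  tie <- structure(list(draws = data.frame(delta_cost = 0,
                                           delta_qaly = 0),
                        wtp = 20000), class = "psa_results")
  expect_equal(ceac(tie, 20000)$probability, 0.5)
  expect_error(ceac(fake, numeric(0)), "non-empty")
})

test_that("quadrant shares sum to one", {
  p <- run_psa(test_config, n = 8, seed = 3)
  s <- summary(p)
  expect_equal(sum(s$quadrant_share), 1)
})
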
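# Synthetic fixtures: life-table generator, random valid configurations,
# degenerate equal-arm configurations and the individual-level
# microsimulation oracle used to validate the cohort engine.

#' Generate a Gompertz life table
#'
#' Annual death probabilities under a Gompertz hazard
#' `h(age) = a * exp(b * age)`:
#' `qx(age) = 1 - exp(-(a/b) * exp(b*age) * (exp(b) - 1))`, with `qx`
#' forced to 1 at the terminal age. The defaults are calibrated by
#' numerical search so that period life expectancy at birth is about 83
#' years, emulating the Spanish general population; the shipped
#' `life_table_es2019_synthetic.csv` is this table.
#'
#' @param a Baseline hazard at age 0 (> 0).
#' @param b Log-hazard slope per year of age (> 0).
#' @param terminal_age Terminal age (default 100).
#' @return A `life_table` (see [load_life_table()]).
#' @export
gompertz_life_table <- function(a = 1.885487252e-05, b = 0.0957,
                                terminal_age = 100) {
  stopifnot(a > 0, b > 0)
  age <- 0:terminal_age
  qx <- 1 - exp(-(a / b) * exp(b * age) * expm1(b))
  qx[length(qx)] <- 1
  load_life_table(data.frame(age = age, qx = qx),
                  terminal_age = terminal_age)
}

#' Random valid model configuration
#'
#' Perturbs every PSA-flagged parameter of a base configuration by its PSA
#' distribution (via [draw_psa_config()]), guaranteeing a configuration
#' that passes full validation. Intended for property-based tests; uses
#' the current RNG state.
#'
#' @param base_config Base `model_config`.
#' @return A validated `model_config`.
#' @export
random_config <- function(base_config) {
  draw_psa_config(base_config)$config
}

#' Equal-arm degenerate configuration
#'
#' Replaces the VKA arm's event rates, P2Y12 shares, unrelated
#' discontinuation and drug cost with apixaban's and zeroes INR
#' monitoring, so that both arms run through bitwise-identical pipelines
#' and all increments are exactly zero.
#'
#' @param config A `model_config`.
#' @return The degenerate `model_config`.
#' @export
equal_arm_config <- function(config) {
  r <- config$rates
  for (ph in PHASES_TX) {
    r$rate[r$phase == ph & r$arm == "vka"] <-
      r$rate[r$phase == ph & r$arm == "apixaban"]
    r$se[r$phase == ph & r$arm == "vka"] <-
      r$se[r$phase == ph & r$arm == "apixaban"]
  }
  config$rates <- r
  i_a <- config$p2y12$arm == "apixaban"
  config$p2y12[!i_a, -1] <- config$p2y12[i_a, -1]
  d <- config$discontinuation
  d$prob[d$kind == "unrelated" & d$key == "vka"] <-
    d$prob[d$kind == "unrelated" & d$key == "apixaban"]
  config$discontinuation <- d
  config$vka_agent <- "apixaban"
  config$monitoring$inr_tests_per_cycle <- 0
  validate_model_config(config)
  config
}

# Per-cycle per-state payoff vectors mirroring the accrual rules of
# summarize_arm(); used by the microsimulation oracle.
microsim_payoffs <- function(config, statics, inputs, arm) {
  n_cycles <- inputs$n_cycles
  n <- statics$n
  st_int <- short_term_by_cycle(inputs)
  on_ind <- statics$is_on
  off_ind <- statics$alive & !statics$is_on

  regimen <- vapply(inputs$phase, function(ph)
    regimen_cost_per_cycle(config, ph, arm), numeric(1))
  pays_drug <- if (config$interruption_cycles >= 1) {
    on_ind & !statics$is_acute
  } else on_ind
  mon_rate <- if (arm == "vka") {
    config$monitoring$inr_tests_per_cycle *
      config$monitoring$inr_cost_per_test
  } else 0
  maint_dir <- state_maintenance_monthly(config, statics,
                                         "maintenance_monthly")
  maint_soc <- state_maintenance_monthly(config, statics,
                                         "societal_monthly")
  months <- 12 * inputs$cycle_length
  ec <- config$event_costs
  st_cost <- stats::setNames(ec$acute, ec$event)[EVENTS_SHORT]

  base_u <- baseline_utility(inputs$age, config$cohort$male_share,
                             config$baseline_utility_coeffs)
  u_ratio <- state_utility_ratios(config, statics)
  acute_r_st <- utility_ratio_table(config, "acute")[EVENTS_SHORT]

  cost <- matrix(0, n_cycles, n)
  util <- matrix(0, n_cycles, n)
  for (t1 in seq_len(n_cycles)) {
    stc <- numeric(n)
    stc[on_ind] <- sum(st_int$on[t1, ] * st_cost)
    stc[off_ind] <- sum(st_int$off[t1, ] * st_cost)
    cost[t1, ] <- regimen[t1] * pays_drug + mon_rate * on_ind +
      months * maint_dir + stc
    adj_on <- prod(1 - st_int$on[t1, ] * (1 - acute_r_st))
    adj_off <- prod(1 - st_int$off[t1, ] * (1 - acute_r_st))
    adj <- ifelse(on_ind, adj_on, ifelse(off_ind, adj_off, 0))
    util[t1, ] <- base_u[t1] * u_ratio * adj
  }
  acute_cost <- stats::setNames(ec$acute, ec$event)[EVENTS_LONG]
  list(cost = cost, util = util, maint_soc = months * maint_soc,
       acute_cost = acute_cost, alive = statics$alive)
}

#' Individual-level microsimulation oracle
#'
#' Simulates individuals cycle by cycle, sampling transitions from the
#' same per-cycle transition structure as the cohort engine and accruing
#' the same discounted costs, life years and QALYs. The cohort trace is
#' the expectation of this process, so agreement within Monte-Carlo error
#' validates the deterministic propagation and accrual.
#'
#' @param config A `model_config`.
#' @param arm `"apixaban"` or `"vka"`.
#' @param n_individuals Number of simulated individuals (>= 1).
#' @param seed Integer RNG seed.
#' @param schedule Optional strategy schedule (default base case).
#' @param horizon Optional cycle count (default lifetime).
#' @return List with `mean` and `se` (each with `ly`, `qaly`,
#'   `cost_payer`), per-cycle mean state `occupancy`, and `n`.
#' @export
microsim_oracle <- function(config, arm, n_individuals, seed = 1,
                            schedule = NULL, horizon = NULL) {
  stopifnot(n_individuals >= 1)
  set.seed(seed)
  n_cycles <- if (is.null(horizon)) horizon_cycles(config) else
    as.integer(horizon)
  if (is.null(schedule)) schedule <- build_schedule(scenario_spec(),
                                                    n_cycles)
  ctx <- engine_context(config, arm, schedule, n_cycles)
  statics <- ctx$statics
  inputs <- ctx$inputs
  pay <- microsim_payoffs(config, statics, inputs, arm)
  disc <- discount_factor(seq_len(n_cycles) - 1L,
                          config$run$discount_rate_annual,
                          config$run$cycle_length_years)
  cl <- config$run$cycle_length_years
  n <- statics$n
  st <- statics$states

  i_mi <- st$id[st$history == "MI" & st$phase == "post_acute" &
                  st$tx %in% "on"]
  i_ef <- st$id[st$phase == "event_free" & st$tx %in% "on"]
  # stratified initial split: the deterministic cohort shares
  n_mi <- round(config$cohort$initial_postacute_mi_share * n_individuals)
  cur <- c(rep(i_mi, n_mi), rep(i_ef, n_individuals - n_mi))

  ly <- numeric(n_individuals)
  qaly <- numeric(n_individuals)
  cost <- numeric(n_individuals)
  occupancy <- matrix(0, n_cycles, n,
                      dimnames = list(NULL, st$name))
  acute_idx <- which(statics$is_acute)
  acute_of <- rep(NA_integer_, n)
  acute_of[acute_idx] <- match(st$acute_event[acute_idx], EVENTS_LONG)

  for (t in seq_len(n_cycles) - 1L) {
    t1 <- t + 1L
    tab <- tabulate(cur, nbins = n)
    occupancy[t1, ] <- tab / n_individuals
    ly <- ly + disc[t1] * cl * pay$alive[cur]
    qaly <- qaly + disc[t1] * cl * pay$util[t1, cur]
    cost <- cost + disc[t1] * pay$cost[t1, cur]
    if (t == n_cycles - 1L) break
    comp <- transition_components(ctx, t)
    Px <- assemble_transition(ctx, comp, expand_death = TRUE)$P
    nxt <- cur
    for (s in which(tab > 0)) {
      if (s == statics$dead_id) next
      members <- which(cur == s)
      dest <- sample.int(n + 4, length(members), replace = TRUE,
                         prob = Px[s, ])
      fatal <- dest > n
      incident <- integer(length(members))
      incident[fatal] <- dest[fatal] - n
      landed_acute <- !fatal & !is.na(acute_of[dest])
      incident[landed_acute] <- acute_of[dest[landed_acute]]
      has_event <- incident > 0
      if (any(has_event)) {
        cost[members[has_event]] <- cost[members[has_event]] +
          disc[t1 + 1L] * pay$acute_cost[incident[has_event]]
      }
      dest[fatal] <- statics$dead_id
      nxt[members] <- dest
    }
    cur <- nxt
  }
  msd <- function(x) c(mean = mean(x), se = stats::sd(x) /
                         sqrt(n_individuals))
  m <- rbind(ly = msd(ly), qaly = msd(qaly), cost_payer = msd(cost))
  list(mean = m[, "mean"], se = m[, "se"], occupancy = occupancy,
       n = n_individuals)
}
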
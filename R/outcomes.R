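#' Discount factor at a cycle
#'
#' Costs and health outcomes are discounted at an annual rate, accrued at
#' cycle start (no half-cycle correction):
#' `(1 + rate)^(-cycle * cycle_length)`.
#'
#' @param cycle Cycle index (0-based), possibly a vector.
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycle_length_years Cycle length in years (default 0.25).
#' @return Discount factor(s).
#' @export
discount_factor <- function(cycle, annual_rate, cycle_length_years = 0.25) {
  stopifnot(annual_rate >= 0)
  (1 + annual_rate)^(-cycle * cycle_length_years)
}

#' General-population baseline utility
#'
#' EQ-5D utility of the general population as a quadratic in age with a
#' sex term, evaluated at the cohort's male share:
#' `intercept + male * male_share + age * a + age2 * a^2`.
#'
#' @param age Age in years (vectorized).
#' @param male_share Proportion male in \[0, 1\].
#' @param coeffs Named coefficients `intercept`, `male`, `age`, `age2`.
#' @return Utility value(s).
#' @export
baseline_utility <- function(age, male_share, coeffs) {
  unname(coeffs["intercept"] + coeffs["male"] * male_share +
           coeffs["age"] * age + coeffs["age2"] * age^2)
}

utility_ratio_table <- function(config, period) {
  u <- config$utilities[config$utilities$period == period, ]
  stats::setNames(u$ratio, u$event)
}

# Static per-state multiplicative utility ratio: acute ratio of the
# incident event times post-acute ratios of the remaining history; dead = 0.
state_utility_ratios <- function(config, statics) {
  st <- statics$states
  acute_r <- utility_ratio_table(config, "acute")
  post_r <- utility_ratio_table(config, "post_acute")
  hist <- state_history_list(st)
  vapply(seq_len(nrow(st)), function(i) {
    if (st$phase[i] == "dead") return(0)
    h <- hist[[i]]
    h <- h[nzchar(h)]
    if (st$phase[i] == "acute") {
      a <- st$acute_event[i]
      return(unname(acute_r[a] * prod(post_r[setdiff(h, a)])))
    }
    if (length(h) == 0) return(1)
    unname(prod(post_r[h]))
  }, numeric(1))
}

# Static per-state monthly maintenance cost (history events in post-acute
# standing: full history for post-acute states, history minus the incident
# event for acute states).
state_maintenance_monthly <- function(config, statics, column) {
  st <- statics$states
  ec <- config$event_costs
  monthly <- stats::setNames(ec[[column]], ec$event)
  hist <- state_history_list(statics$states)
  vapply(seq_len(nrow(st)), function(i) {
    if (st$phase[i] == "dead") return(0)
    h <- hist[[i]]
    h <- h[nzchar(h)]
    if (st$phase[i] == "acute") h <- setdiff(h, st$acute_event[i])
    if (length(h) == 0) return(0)
    sum(monthly[h])
  }, numeric(1))
}

#' Per-cycle utility weight of a single state
#'
#' Baseline general-population utility at the cohort's age that cycle,
#' multiplied by the acute event:control ratio when the state is acute, the
#' post-acute ratios of history events in post-acute standing, and
#' intensity-weighted one-cycle ratios for short-term events. Dead is 0.
#'
#' @param state State id or name.
#' @param cycle Cycle index (0-based).
#' @param short_term_intensities Length-3 vector of that cycle's CRNMB,
#'   REV, SE probabilities for this state (default 0).
#' @param config A `model_config`.
#' @return Utility weight.
#' @export
state_utility <- function(state, cycle, config,
                          short_term_intensities = c(0, 0, 0)) {
  statics <- state_statics(config)
  if (is.character(state)) state <- match(state, statics$states$name)
  ratios <- state_utility_ratios(config, statics)
  age <- config$cohort$start_age + config$run$cycle_length_years * cycle
  base <- baseline_utility(age, config$cohort$male_share,
                           config$baseline_utility_coeffs)
  acute_r <- utility_ratio_table(config, "acute")[EVENTS_SHORT]
  st_adj <- prod(1 - short_term_intensities * (1 - acute_r))
  base * ratios[state] * st_adj
}

# Short-term intensities by treatment status for every cycle: a (cycles x
# 3 x {on, off}) pair of matrices.
short_term_by_cycle <- function(inputs) {
  cl <- inputs$cycle_length
  on <- 1 - exp(-(inputs$rates_on[, EVENTS_SHORT, drop = FALSE] / 100) * cl)
  off_rates <- inputs$rates_off[EVENTS_SHORT]
  off <- matrix(1 - exp(-(off_rates / 100) * cl), inputs$n_cycles, 3,
                byrow = TRUE, dimnames = list(NULL, EVENTS_SHORT))
  list(on = on, off = off)
}

#' Discounted cost components of one cycle
#'
#' Drug acquisition cost (on-treatment occupancy, net of the one-cycle
#' interruption haircut for patients in an acute state, times the
#' phase-specific regimen cost), INR monitoring (VKA arm only), acute
#' event costs (incident long-term events times DRG tariffs plus
#' short-term intensities times their one-off costs), post-acute
#' maintenance, and, under the societal perspective, indirect acute and
#' maintenance costs for IS/ICH. All components are discounted to cycle 0.
#'
#' @param trace A `cohort_trace`.
#' @param cycle Cycle index (0-based).
#' @param config A `model_config`.
#' @param perspective `"payer"` or `"societal"`.
#' @return Named vector of discounted euro components.
#' @export
cycle_costs <- function(trace, cycle, config, perspective = "payer") {
  if (!perspective %in% c("payer", "societal")) {
    stop("unknown perspective: ", perspective)
  }
  res <- summarize_arm(trace, config, by_cycle = TRUE)
  comp <- res$by_cycle[cycle + 1L, ]
  out <- c(treatment = comp$treatment, monitoring = comp$monitoring,
           acute = comp$acute_direct, maintenance = comp$maintenance_direct)
  if (perspective == "societal") {
    out <- c(out, indirect_acute = comp$acute_indirect,
             indirect_maintenance = comp$maintenance_indirect)
  }
  out
}

#' Summarize a cohort trace into per-arm results
#'
#' Accrues discounted costs by component (treatment, monitoring, acute,
#' post-acute maintenance, indirect acute/maintenance), discounted life
#' years and QALYs, cumulative events per 100 patients, and discounted
#' time on/off treatment (so that time on plus time off equals total
#' life years).
#'
#' @param trace A `cohort_trace`.
#' @param config A `model_config`.
#' @param by_cycle Also return the per-cycle component matrix.
#' @return An `arm_results` object.
#' @export
summarize_arm <- function(trace, config, by_cycle = FALSE) {
  statics <- trace$statics
  st <- statics$states
  n_cycles <- trace$n_cycles
  occ <- trace$occupancy
  cl <- config$run$cycle_length_years
  cycles <- seq_len(n_cycles) - 1L
  disc <- discount_factor(cycles, config$run$discount_rate_annual, cl)

  alive <- as.numeric(statics$alive)
  on_ind <- as.numeric(statics$is_on)
  off_ind <- as.numeric(statics$alive & !statics$is_on)
  acute_ind <- as.numeric(statics$is_acute)

  inputs <- if (!is.null(trace$inputs)) trace$inputs else
    cycle_inputs(config, trace$arm, trace$schedule, n_cycles)
  st_int <- short_term_by_cycle(inputs)

  # treatment: regimen cost by phase, acute states interrupted
  phase_cost <- vapply(unique(inputs$phase), function(ph)
    regimen_cost_per_cycle(config, ph, trace$arm), numeric(1))
  regimen <- phase_cost[inputs$phase]
  pays_drug <- if (config$interruption_cycles >= 1) {
    on_ind * (1 - acute_ind)
  } else on_ind
  treatment_t <- regimen * as.numeric(occ %*% pays_drug)

  monitoring_t <- if (trace$arm == "vka") {
    config$monitoring$inr_tests_per_cycle *
      config$monitoring$inr_cost_per_test * as.numeric(occ %*% on_ind)
  } else rep(0, n_cycles)

  ec <- config$event_costs
  acute_cost <- stats::setNames(ec$acute, ec$event)
  soc_acute <- stats::setNames(ec$societal_acute, ec$event)
  occ_on <- as.numeric(occ %*% on_ind)
  occ_off <- as.numeric(occ %*% off_ind)
  st_counts <- occ_on * st_int$on + occ_off * st_int$off
  acute_lt_t <- as.numeric(trace$events %*% acute_cost[EVENTS_LONG])
  acute_st_t <- as.numeric(st_counts %*% acute_cost[EVENTS_SHORT])
  acute_ind_t <- as.numeric(trace$events %*% soc_acute[EVENTS_LONG]) +
    as.numeric(st_counts %*% soc_acute[EVENTS_SHORT])

  maint_dir <- state_maintenance_monthly(config, statics,
                                         "maintenance_monthly")
  maint_soc <- state_maintenance_monthly(config, statics,
                                         "societal_monthly")
  months <- 12 * cl
  maintenance_t <- months * as.numeric(occ %*% maint_dir)
  maintenance_ind_t <- months * as.numeric(occ %*% maint_soc)

  # utilities: baseline(age) x state ratio x short-term adjustment
  base_u <- baseline_utility(inputs$age, config$cohort$male_share,
                             config$baseline_utility_coeffs)
  u_ratio <- state_utility_ratios(config, statics)
  acute_r_st <- utility_ratio_table(config, "acute")[EVENTS_SHORT]
  adj_on <- apply(1 - st_int$on *
                    matrix(1 - acute_r_st, n_cycles, 3, byrow = TRUE),
                  1, prod)
  adj_off <- apply(1 - st_int$off *
                     matrix(1 - acute_r_st, n_cycles, 3, byrow = TRUE),
                   1, prod)
  util_occ <- as.numeric((occ * matrix(u_ratio, n_cycles, statics$n,
                                       byrow = TRUE)) %*% on_ind) * adj_on +
    as.numeric((occ * matrix(u_ratio, n_cycles, statics$n,
                             byrow = TRUE)) %*% off_ind) * adj_off
  qaly_t <- cl * base_u * util_occ
  ly_t <- cl * as.numeric(occ %*% alive)

  events_cum <- colSums(trace$events)
  st_cum <- colSums(st_counts)

  comp <- data.frame(
    cycle = cycles,
    treatment = disc * treatment_t,
    monitoring = disc * monitoring_t,
    acute_direct = disc * (acute_lt_t + acute_st_t),
    maintenance_direct = disc * maintenance_t,
    acute_indirect = disc * acute_ind_t,
    maintenance_indirect = disc * maintenance_ind_t,
    ly = disc * ly_t,
    qaly = disc * qaly_t)

  res <- structure(list(
    arm = trace$arm,
    costs = c(treatment = sum(comp$treatment),
              monitoring = sum(comp$monitoring),
              acute_direct = sum(comp$acute_direct),
              maintenance_direct = sum(comp$maintenance_direct),
              acute_indirect = sum(comp$acute_indirect),
              maintenance_indirect = sum(comp$maintenance_indirect)),
    total_ly = sum(comp$ly),
    total_qaly = sum(comp$qaly),
    events_per_100 = 100 * c(events_cum, st_cum)[EVENTS_ALL],
    time_on_treatment = cl * sum(disc * occ_on),
    time_off_treatment = cl * sum(disc * occ_off)
  ), class = "arm_results")
  res$total_cost_payer <- sum(res$costs[c("treatment", "monitoring",
                                          "acute_direct",
                                          "maintenance_direct")])
  res$total_cost_societal <- res$total_cost_payer +
    res$costs["acute_indirect"] + res$costs["maintenance_indirect"]
  res$total_cost_societal <- unname(res$total_cost_societal)
  if (by_cycle) res$by_cycle <- comp
  res
}

#' @export
print.arm_results <- function(x, ...) {
  cat("<arm_results>", x$arm, "\n")
  cat(sprintf("  total cost (payer)    EUR %10.2f\n", x$total_cost_payer))
  cat(sprintf("  total cost (societal) EUR %10.2f\n",
              x$total_cost_societal))
  cat(sprintf("  LYs %.2f | QALYs %.2f | years on/off tx %.2f/%.2f\n",
              x$total_ly, x$total_qaly, x$time_on_treatment,
              x$time_off_treatment))
  invisible(x)
}

#' Incremental cost-effectiveness of apixaban versus VKA
#'
#' Deltas are apixaban minus VKA. `INMB = WTP x dQALY - dCost`,
#' `INHB = INMB / WTP`; the dominance class follows the cost-effectiveness
#' plane quadrant and the WTP threshold.
#'
#' @param apixaban,vka `arm_results` for the two arms.
#' @param wtp Willingness-to-pay threshold in euro per QALY.
#' @param perspective `"payer"` or `"societal"`.
#' @return An `incremental_results` object.
#' @export
incremental <- function(apixaban, vka, wtp = 20000,
                        perspective = "payer") {
  total <- function(a) if (perspective == "payer") a$total_cost_payer else
    a$total_cost_societal
  d_cost <- total(apixaban) - total(vka)
  d_ly <- apixaban$total_ly - vka$total_ly
  d_qaly <- apixaban$total_qaly - vka$total_qaly
  inmb <- wtp * d_qaly - d_cost
  icer <- if (d_qaly != 0) d_cost / d_qaly else NA_real_
  dominance <- if (d_qaly > 0 && d_cost < 0) "dominant"
  else if (d_qaly < 0 && d_cost > 0) "dominated"
  else if (d_qaly > 0 && d_cost >= 0) {
    if (icer <= wtp) "cost_effective" else "not_cost_effective"
  } else if (d_qaly < 0 && d_cost <= 0) "SW-tradeoff"
  else "equivalent"
  structure(list(
    perspective = perspective, wtp = wtp,
    delta_cost = d_cost, delta_ly = d_ly, delta_qaly = d_qaly,
    delta_events_per_100 = apixaban$events_per_100 - vka$events_per_100,
    icer = icer, inmb = inmb, inhb = inmb / wtp,
    dominance = dominance
  ), class = "incremental_results")
}

#' @export
print.incremental_results <- function(x, ...) {
  cat("<incremental_results> apixaban vs VKA,", x$perspective,
      "perspective\n")
  cat(sprintf("  dCost EUR %.2f | dLY %.4f | dQALY %.4f\n",
              x$delta_cost, x$delta_ly, x$delta_qaly))
  icer_lab <- if (x$dominance %in% c("dominant", "dominated")) x$dominance
  else sprintf("%.0f EUR/QALY", x$icer)
  cat(sprintf("  ICER: %s | INMB EUR %.2f | INHB %.4f QALY (WTP %d)\n",
              icer_lab, x$inmb, x$inhb, x$wtp))
  invisible(x)
}

#' Run both arms of the base case and compute increments
#'
#' @param config A `model_config`.
#' @param schedule Optional schedule override (default base-case strategy).
#' @param horizon Optional cycle-count override.
#' @return List with `apixaban` and `vka` `arm_results` and
#'   `incremental_payer` / `incremental_societal`.
#' @export
run_base_case <- function(config, schedule = NULL, horizon = NULL) {
  apix <- summarize_arm(run_trace(config, "apixaban", schedule, horizon),
                        config)
  vka <- summarize_arm(run_trace(config, "vka", schedule, horizon), config)
  list(apixaban = apix, vka = vka,
       incremental_payer = incremental(apix, vka, config$run$wtp, "payer"),
       incremental_societal = incremental(apix, vka, config$run$wtp,
                                          "societal"))
}

#' Table-shaped summary of a base-case run
#'
#' @param result Output of [run_base_case()].
#' @return Data frame with one row per reported quantity (events per 100
#'   patients, cost components, health outcomes) and columns for each arm
#'   and the net difference.
#' @export
base_case_table <- function(result) {
  a <- result$apixaban; v <- result$vka
  bleeding <- c("ICH", "OMB", "CRNMB")
  ischemic <- c("MI", "IS", "REV", "SE")
  row <- function(label, x, y) data.frame(
    quantity = label, apixaban = x, vka = y, difference = x - y)
  rbind(
    row("Bleeding events per 100", sum(a$events_per_100[bleeding]),
        sum(v$events_per_100[bleeding])),
    do.call(rbind, lapply(bleeding, function(e)
      row(paste0("  ", e), a$events_per_100[e], v$events_per_100[e]))),
    row("Ischemic events per 100", sum(a$events_per_100[ischemic]),
        sum(v$events_per_100[ischemic])),
    do.call(rbind, lapply(ischemic, function(e)
      row(paste0("  ", e), a$events_per_100[e], v$events_per_100[e]))),
    row("Treatment costs", a$costs["treatment"], v$costs["treatment"]),
    row("Monitoring costs", a$costs["monitoring"], v$costs["monitoring"]),
    row("Acute costs", a$costs["acute_direct"], v$costs["acute_direct"]),
    row("Post-acute costs", a$costs["maintenance_direct"],
        v$costs["maintenance_direct"]),
    row("Total costs (payer)", a$total_cost_payer, v$total_cost_payer),
    row("Indirect acute costs", a$costs["acute_indirect"],
        v$costs["acute_indirect"]),
    row("Indirect post-acute costs", a$costs["maintenance_indirect"],
        v$costs["maintenance_indirect"]),
    row("Total costs (societal)", a$total_cost_societal,
        v$total_cost_societal),
    row("Total LYs", a$total_ly, v$total_ly),
    row("Total QALYs", a$total_qaly, v$total_qaly),
    row("Time on treatment (years)", a$time_on_treatment,
        v$time_on_treatment),
    row("Time off treatment (years)", a$time_off_treatment,
        v$time_off_treatment)
  )
}
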
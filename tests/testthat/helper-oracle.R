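# Independent brute-force transition-row builder. Recomputes one origin
# state's destination probabilities with plain scalar code straight from
# the configuration tables (no shared engine internals), so the engine's
# vectorized rate math can be checked against it.
brute_force_row <- function(config, state_name, cycle, schedule,
                            arm = "apixaban") {
  states <- enumerate_states()
  i <- match(state_name, states$name)
  stopifnot(!is.na(i))
  n <- nrow(states)
  row <- stats::setNames(numeric(n), states$name)
  if (states$phase[i] == "dead") {
    row["dead"] <- 1
    return(row)
  }
  cl <- config$run$cycle_length_years
  age <- config$cohort$start_age + cl * cycle
  phase <- schedule$phase[schedule$start <= cycle & cycle < schedule$end]
  history <- strsplit(states$history[i], "+", fixed = TRUE)[[1]]
  history <- history[nzchar(history)]
  on <- states$tx[i] == "on"

  rates <- if (on) event_rates(config, phase, arm) else
    event_rates(config, "off", arm)

  permitted <- if (length(history) >= 2) history else
    c("OMB", "MI", "IS", "ICH")
  ref_age <- config$cohort$start_age + 0.5
  lam <- numeric(0)
  for (e in permitted) {
    a <- if (age > ref_age) config$aging_hr[e]^((age - ref_age) / 10) else 1
    h <- 1
    for (p in history) h <- h * config$subsequent_hr[p, e]
    lam[e] <- rates[e] / 100 * a * h
  }
  tot <- sum(lam)
  p_evt <- if (tot > 0) lam / tot * (1 - exp(-tot * cl)) else lam * 0

  mort_hr <- if (length(history) == 0) config$mortality_hr["event_free"]
  else prod(config$mortality_hr[history])
  qx <- life_table_qx(config$life_table, age)
  p_bg <- 1 - (1 - qx)^(cl * mort_hr)

  d <- config$discontinuation
  p_u <- if (on) d$prob[d$kind == "unrelated" & d$key == arm] else 0

  find_state <- function(history, phase, acute_event, tx) {
    key <- paste(c("OMB", "MI", "IS", "ICH")[
      c("OMB", "MI", "IS", "ICH") %in% history], collapse = "+")
    hit <- states$history == key & states$phase == phase &
      (is.na(acute_event) | states$acute_event %in% acute_event) &
      states$tx %in% tx
    states$name[hit]
  }

  death <- 0
  for (e in permitted) {
    cfr <- event_fatality(e, age, config$fatality)
    d_e <- 1 - (1 - cfr) * (1 - p_bg)
    surv <- p_evt[e] * (1 - d_e)
    death <- death + p_evt[e] * d_e
    p_de <- d$prob[d$kind == "event" & d$key == e]
    q <- if (on) 1 - (1 - p_u) * (1 - p_de) else 0
    h2 <- union(history, e)
    row[find_state(h2, "acute", e, "on")] <-
      row[find_state(h2, "acute", e, "on")] + if (on) surv * (1 - q) else 0
    row[find_state(h2, "acute", e, "off")] <-
      row[find_state(h2, "acute", e, "off")] +
      if (on) surv * q else surv
  }
  p0 <- 1 - sum(p_evt)
  death <- death + p0 * p_bg
  surv0 <- p0 * (1 - p_bg)
  next_phase <- if (states$phase[i] == "acute") "post_acute" else
    states$phase[i]
  nxt_on <- find_state(history, next_phase,
                       if (next_phase == "acute") states$acute_event[i]
                       else NA, "on")
  nxt_off <- find_state(history, next_phase,
                        if (next_phase == "acute") states$acute_event[i]
                        else NA, "off")
  if (on) {
    row[nxt_on] <- row[nxt_on] + surv0 * (1 - p_u)
    row[nxt_off] <- row[nxt_off] + surv0 * p_u
  } else {
    row[nxt_off] <- row[nxt_off] + surv0
  }
  row["dead"] <- death
  row
}
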
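# Transition engine: builds per-cycle competing-risk transition structure
# from rates, hazard-ratio multipliers, case-fatality rates and the life
# table, and propagates the cohort.

# Config-independent structure of the state space (destination indices,
# permitted events, off-treatment twins, no-event successors). Cached for
# the life of the session: it never changes.
.state_structure_cache <- new.env(parent = emptyenv())

state_structure <- function() {
  if (!is.null(.state_structure_cache$struct)) {
    return(.state_structure_cache$struct)
  }
  states <- enumerate_states()
  n <- nrow(states)
  hist <- state_history_list(states)
  alive <- states$phase != "dead"
  dead_id <- states$id[states$phase == "dead"]

  allowed <- matrix(FALSE, n, 4, dimnames = list(NULL, EVENTS_LONG))
  dest <- matrix(NA_integer_, n, 4, dimnames = list(NULL, EVENTS_LONG))

  state_idx <- function(history_key, phase, acute_event, tx) {
    hit <- states$history == history_key & states$phase == phase &
      (is.na(acute_event) | states$acute_event %in% acute_event) &
      states$tx %in% tx
    states$id[hit]
  }
  hist_key <- function(ev) paste(EVENTS_LONG[EVENTS_LONG %in% ev],
                                 collapse = "+")

  for (i in which(alive)) {
    h <- hist[[i]]
    permitted <- if (length(h) >= 2) h else EVENTS_LONG
    for (e in permitted) {
      allowed[i, e] <- TRUE
      dest[i, e] <- state_idx(hist_key(union(h, e)), "acute", e,
                              states$tx[i])
    }
  }

  off_twin <- rep(NA_integer_, n)
  for (i in which(alive & states$tx == "on")) {
    off_twin[i] <- state_idx(states$history[i], states$phase[i],
                             if (is.na(states$acute_event[i])) NA else
                               states$acute_event[i], "off")
  }

  next_no_event <- states$id
  for (i in which(states$phase == "acute")) {
    next_no_event[i] <- state_idx(states$history[i], "post_acute", NA,
                                  states$tx[i])
  }
  next_no_event[!alive] <- dead_id

  # history as up-to-two event indices (0 = none), for vectorized
  # config-dependent multipliers
  hidx <- t(vapply(hist, function(h) {
    h <- h[nzchar(h)]
    k <- match(h, EVENTS_LONG)
    c(if (length(k) >= 1) k[1] else 0L, if (length(k) >= 2) k[2] else 0L)
  }, integer(2)))

  struct <- list(states = states, n = n, alive = alive, dead_id = dead_id,
                 allowed = allowed, dest = dest, off_twin = off_twin,
                 next_no_event = next_no_event, hidx = hidx,
                 is_acute = states$phase == "acute",
                 is_on = !is.na(states$tx) & states$tx == "on")
  .state_structure_cache$struct <- struct
  struct
}

# Static per-state structures for one configuration: the cached state
# structure plus history multipliers and excess-mortality HRs.
state_statics <- function(config) {
  s <- state_structure()
  h1 <- s$hidx[, 1]
  h2 <- s$hidx[, 2]
  hist_mult <- matrix(1, s$n, 4, dimnames = list(NULL, EVENTS_LONG))
  for (k in 1:4) {
    col <- config$subsequent_hr[, EVENTS_LONG[k]]
    hist_mult[, k] <- ifelse(h1 > 0, col[h1], 1) *
      ifelse(h2 > 0, col[h2], 1)
  }

  # Excess mortality vs the general population: event-free carries the
  # prior-ACS/PCI HR; histories multiply per-event HRs (OMB contributes
  # the event-free value because no OMB-specific excess mortality is
  # published, so the pack lists OMB = event-free).
  mhr_e <- config$mortality_hr[EVENTS_LONG]
  mort_hr <- ifelse(h1 > 0, mhr_e[h1], config$mortality_hr["event_free"]) *
    ifelse(h2 > 0, mhr_e[h2], 1)
  mort_hr[!s$alive] <- 1

  c(s, list(hist_mult = hist_mult, mort_hr = unname(mort_hr)))
}

# Pre-computes everything that varies by cycle but not by state:
# treatment phase, age, aging multipliers, background qx, age-banded CFRs,
# on-treatment rates by phase, off-treatment rates, discontinuation.
cycle_inputs <- function(config, arm, schedule, n_cycles) {
  cl <- config$run$cycle_length_years
  t <- seq_len(n_cycles) - 1L
  age <- config$cohort$start_age + cl * t
  ref_age <- config$cohort$start_age + 0.5

  phase <- character(n_cycles)
  for (i in seq_len(nrow(schedule))) {
    sel <- t >= schedule$start[i] & t < schedule$end[i]
    phase[sel] <- schedule$phase[i]
  }
  if (any(!nzchar(phase))) stop("schedule does not cover the horizon")

  aging <- matrix(1, n_cycles, 4, dimnames = list(NULL, EVENTS_LONG))
  for (e in EVENTS_LONG) {
    grow <- age > ref_age
    aging[grow, e] <- config$aging_hr[e]^((age[grow] - ref_age) / 10)
  }

  qx <- life_table_qx(config$life_table, age)

  cfr <- matrix(0, n_cycles, 4, dimnames = list(NULL, EVENTS_LONG))
  for (e in EVENTS_LONG) {
    b <- config$fatality[config$fatality$event == e, ]
    b <- b[order(b$age_lo), ]
    cfr[, e] <- b$cfr[findInterval(pmax(age, b$age_lo[1]), b$age_lo)]
  }

  rates_on <- matrix(0, n_cycles, 7, dimnames = list(NULL, EVENTS_ALL))
  for (ph in unique(phase)) {
    rates_on[phase == ph, ] <- matrix(event_rates(config, ph, arm),
                                      sum(phase == ph), 7, byrow = TRUE)
  }
  rates_off <- event_rates(config, "off", arm)

  d <- config$discontinuation
  p_dis_u <- d$prob[d$kind == "unrelated" & d$key == arm]
  p_dis_evt <- stats::setNames(rep(0, 4), EVENTS_LONG)
  de <- d[d$kind == "event", ]
  p_dis_evt[de$key] <- de$prob

  list(n_cycles = n_cycles, age = age, phase = phase, aging = aging,
       qx = qx, cfr = cfr, rates_on = rates_on, rates_off = rates_off,
       p_dis_u = p_dis_u, p_dis_evt = p_dis_evt, cycle_length = cl)
}

# Per-run engine context: statics, cycle inputs, per-phase hazard bases
# (rate x history multiplier, per person-year), per-phase short-term
# intensities, and linear-index assembly plans.
engine_context <- function(config, arm, schedule, n_cycles,
                           statics = NULL) {
  if (is.null(statics)) statics <- state_statics(config)
  inputs <- cycle_inputs(config, arm, schedule, n_cycles)
  n <- statics$n

  lam_base <- list()
  st_base <- list()
  for (ph in unique(inputs$phase)) {
    r_on <- event_rates(config, ph, arm)
    r_off <- inputs$rates_off
    rate_state <- matrix(r_off[EVENTS_LONG], n, 4, byrow = TRUE)
    rate_state[statics$is_on, ] <- matrix(r_on[EVENTS_LONG],
                                          sum(statics$is_on), 4,
                                          byrow = TRUE)
    lb <- (rate_state / 100) * statics$hist_mult
    lb[!statics$allowed] <- 0
    lb[!statics$alive, ] <- 0
    lam_base[[ph]] <- lb
    stv <- matrix(1 - exp(-(r_off[EVENTS_SHORT] / 100) *
                            inputs$cycle_length), n, 3, byrow = TRUE,
                  dimnames = list(NULL, EVENTS_SHORT))
    stv[statics$is_on, ] <- matrix(
      1 - exp(-(r_on[EVENTS_SHORT] / 100) * inputs$cycle_length),
      sum(statics$is_on), 3, byrow = TRUE)
    stv[!statics$alive, ] <- 0
    st_base[[ph]] <- stv
  }

  # assembly plans: static origin sets and linear indices into the n x n
  # transition matrix (and its n+4-column expanded variant)
  plan_evt <- lapply(seq_along(EVENTS_LONG), function(k) {
    s <- which(statics$alive & statics$allowed[, k])
    dest <- statics$dest[s, k]
    on <- statics$is_on[s]
    q <- ifelse(on, 1 - (1 - inputs$p_dis_u) *
                  (1 - inputs$p_dis_evt[k]), 0)
    dest_off <- ifelse(on, statics$off_twin[dest], NA_integer_)
    list(s = s, lin = (dest - 1L) * n + s,
         lin_x = (dest - 1L) * n + s,
         so = which(on),
         lin_off = (dest_off[on] - 1L) * n + s[on],
         q = q, k = k)
  })
  s0 <- which(statics$alive)
  on0 <- statics$is_on[s0]
  nxt <- statics$next_no_event[s0]
  plan0 <- list(s = s0, lin = (nxt - 1L) * n + s0,
                so = which(on0),
                lin_off = (statics$off_twin[nxt[on0]] - 1L) * n + s0[on0],
                stay_frac = ifelse(on0, 1 - inputs$p_dis_u, 1))

  list(statics = statics, inputs = inputs, lam_base = lam_base,
       st_base = st_base, plan_evt = plan_evt, plan0 = plan0, n = n)
}

# Per-cycle, per-state transition pieces shared by the cohort engine, the
# exported single-row builder and the microsimulation oracle.
transition_components <- function(ctx, cycle) {
  t1 <- cycle + 1L
  inputs <- ctx$inputs
  statics <- ctx$statics
  cl <- inputs$cycle_length
  ph <- inputs$phase[t1]

  lam <- ctx$lam_base[[ph]] *
    rep(inputs$aging[t1, ], each = ctx$n)
  tot <- rowSums(lam)
  p_any <- 1 - exp(-tot * cl)
  share <- lam / ifelse(tot > 0, tot, 1)
  p_evt <- share * p_any
  p_stay <- 1 - rowSums(p_evt)

  p_bg <- background_death_prob(inputs$qx[t1], statics$mort_hr, cl)
  p_bg[!statics$alive] <- 0

  list(p_evt = p_evt, p_stay = p_stay, p_st = ctx$st_base[[ph]],
       p_bg = p_bg, cfr = inputs$cfr[t1, ], p_dis_u = inputs$p_dis_u,
       p_dis_evt = inputs$p_dis_evt)
}

# Assembles the dense transition matrix P (n x n) and the incident
# long-term event matrix E (n x 4, counted before the fatality split)
# from the per-cycle components. With expand_death = TRUE, P gains four
# extra columns (death caused by each long-term event) and the dead
# column carries background death only, so the microsimulation oracle can
# register fatal incident events.
assemble_transition <- function(ctx, comp, expand_death = FALSE) {
  n <- ctx$n
  statics <- ctx$statics
  dead <- statics$dead_id
  ncol_p <- if (expand_death) n + 4L else n
  P <- matrix(0, n, ncol_p)
  death <- numeric(n)

  for (pl in ctx$plan_evt) {
    s <- pl$s
    p_e <- comp$p_evt[s, pl$k]
    d_e <- 1 - (1 - comp$cfr[pl$k]) * (1 - comp$p_bg[s])
    surv <- p_e * (1 - d_e)
    if (expand_death) {
      P[(n + pl$k - 1L) * n + s] <- p_e * d_e
    } else {
      death[s] <- death[s] + p_e * d_e
    }
    P[pl$lin] <- P[pl$lin] + surv * (1 - pl$q)
    P[pl$lin_off] <- P[pl$lin_off] + surv[pl$so] * pl$q[pl$so]
  }

  pl <- ctx$plan0
  s <- pl$s
  p0 <- comp$p_stay[s]
  death[s] <- death[s] + p0 * comp$p_bg[s]
  surv0 <- p0 * (1 - comp$p_bg[s])
  P[pl$lin] <- P[pl$lin] + surv0 * pl$stay_frac
  P[pl$lin_off] <- P[pl$lin_off] + surv0[pl$so] * (1 - pl$stay_frac[pl$so])
  P[(dead - 1L) * n + seq_len(n)] <- P[(dead - 1L) * n + seq_len(n)] +
    death
  P[dead, ] <- 0
  P[dead, dead] <- 1

  E <- comp$p_evt
  E[!statics$alive, ] <- 0
  list(P = P, E = E, ST = comp$p_st)
}

#' Build one transition row
#'
#' Combines phase-specific event rates (scaled by aging and history
#' multipliers and converted by the competing-risk formula), acute-cycle
#' case fatality, background mortality with the state's excess-mortality
#' hazard ratio, acute-to-post-acute progression, and event-related plus
#' per-cycle unrelated treatment discontinuation, into the probability row
#' of one origin state at one cycle. Death is combined across independent
#' causes as `1 - prod(1 - p_k)`.
#'
#' @param state State id (integer) or state name from [enumerate_states()].
#' @param cycle Cycle index (0-based).
#' @param schedule A strategy schedule from [build_schedule()].
#' @param config A `model_config`.
#' @param arm `"apixaban"` or `"vka"`.
#' @return Named probability vector over destination states (sums to 1),
#'   with the cycle's short-term event intensities for that origin in
#'   attribute `"short_term"`.
#' @export
build_transition_row <- function(state, cycle, schedule, config,
                                 arm = "apixaban") {
  ctx <- engine_context(config, arm, schedule, cycle + 1L)
  if (is.character(state)) state <- match(state, ctx$statics$states$name)
  stopifnot(!is.na(state), state >= 1, state <= ctx$n)
  comp <- transition_components(ctx, cycle)
  tr <- assemble_transition(ctx, comp)
  row <- stats::setNames(tr$P[state, ], ctx$statics$states$name)
  if (abs(sum(row) - 1) > 1e-12) {
    stop("transition row failed to normalize: sum = ", sum(row))
  }
  attr(row, "short_term") <- tr$ST[state, ]
  row
}

#' Run the Markov cohort trace
#'
#' Propagates the cohort from the initial split (61.2% post-acute MI, the
#' remainder event-free, all on treatment) through the cycle-specific
#' transition matrices. Occupancy rows are recorded for cycles
#' `0 .. horizon-1`; incident long-term events arriving at cycle t are
#' recorded in row t of the event matrix (row 0 is zero), and short-term
#' intensities are recorded against the cycle in which they occur.
#'
#' @param config A `model_config`.
#' @param arm `"apixaban"` or `"vka"`.
#' @param schedule Strategy schedule; default is the base-case strategy
#'   (blended triple-or-dual for 6 months, then monotherapy).
#' @param horizon Number of cycles (default: lifetime, to age 100).
#' @return A `cohort_trace` object with `occupancy` (cycles x states),
#'   `events` (cycles x 4 long-term events), `short_term` (cycles x 3),
#'   `ages`, `phases`, and the state table.
#' @export
run_trace <- function(config, arm, schedule = NULL, horizon = NULL) {
  n_cycles <- if (is.null(horizon)) horizon_cycles(config) else
    as.integer(horizon)
  stopifnot(n_cycles >= 1)
  if (is.null(schedule)) schedule <- build_schedule(scenario_spec(),
                                                    n_cycles)
  ctx <- engine_context(config, arm, schedule, n_cycles)
  statics <- ctx$statics
  n <- ctx$n

  occ <- matrix(0, n_cycles, n,
                dimnames = list(NULL, statics$states$name))
  events <- matrix(0, n_cycles, 4, dimnames = list(NULL, EVENTS_LONG))
  st <- matrix(0, n_cycles, 3, dimnames = list(NULL, EVENTS_SHORT))

  sdf <- statics$states
  i_mi <- sdf$id[sdf$history == "MI" & sdf$phase == "post_acute" &
                   sdf$tx %in% "on"]
  i_ef <- sdf$id[sdf$phase == "event_free" & sdf$tx %in% "on"]
  occ[1, i_mi] <- config$cohort$initial_postacute_mi_share
  occ[1, i_ef] <- 1 - config$cohort$initial_postacute_mi_share

  for (t in seq_len(n_cycles) - 1L) {
    comp <- transition_components(ctx, t)
    tr <- assemble_transition(ctx, comp)
    st[t + 1L, ] <- occ[t + 1L, ] %*% tr$ST
    if (t < n_cycles - 1L) {
      events[t + 2L, ] <- occ[t + 1L, ] %*% tr$E
      occ[t + 2L, ] <- occ[t + 1L, ] %*% tr$P
    }
  }

  structure(list(occupancy = occ, events = events, short_term = st,
                 ages = ctx$inputs$age, phases = ctx$inputs$phase,
                 states = statics$states, statics = statics,
                 inputs = ctx$inputs,
                 schedule = schedule, arm = arm, n_cycles = n_cycles),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  dead <- x$occupancy[x$n_cycles, x$statics$dead_id]
  cat("<cohort_trace> arm:", x$arm, "|", x$n_cycles, "cycles |",
      "final dead share:", round(dead, 4), "\n")
  invisible(x)
}

#' Export a cohort trace as data frames
#'
#' @param trace A `cohort_trace`.
#' @return List of two data frames: `occupancy` (cycle x state) and
#'   `incidence` (cycle x event, long- and short-term).
#' @export
trace_as_data_frames <- function(trace) {
  occ <- data.frame(cycle = seq_len(trace$n_cycles) - 1L,
                    age = trace$ages, trace$occupancy,
                    check.names = FALSE)
  inc <- data.frame(cycle = seq_len(trace$n_cycles) - 1L,
                    trace$events, trace$short_term, check.names = FALSE)
  list(occupancy = occ, incidence = inc)
}
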
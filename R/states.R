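#' Enumerate the health-state space
#'
#' Builds the 55-state space: 27 alive shapes (1 event-free + 8 singleton
#' acute/post-acute + 12 two-event acute + 6 two-event post-acute) crossed
#' with treatment status (on/off), plus the absorbing dead state. Acute
#' states carry the incident event in their history; recurrent events map
#' back to the existing acute state for that (event, history); after two
#' concomitant events only those same two events can recur.
#'
#' The ordering is deterministic: all on-treatment states, then their
#' off-treatment twins in the same order, then `dead`. Within a treatment
#' status: event-free; singleton acute then post-acute by event
#' (OMB, MI, IS, ICH); two-event acute by history pair then acute event;
#' two-event post-acute by pair.
#'
#' @return A `state_space` data frame with columns `id`, `name`, `history`
#'   (e.g. `"MI+IS"`), `phase` (`event_free`, `acute`, `post_acute`,
#'   `dead`), `acute_event`, `tx` (`on`/`off`/`NA`).
#' @export
enumerate_states <- function() {
  hist_key <- function(ev) paste(EVENTS_LONG[EVENTS_LONG %in% ev],
                                 collapse = "+")
  rows <- list()
  add <- function(history, phase, acute_event = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      history = history, phase = phase, acute_event = acute_event,
      stringsAsFactors = FALSE)
  }
  add("", "event_free")
  for (e in EVENTS_LONG) add(e, "acute", e)
  for (e in EVENTS_LONG) add(e, "post_acute")
  pairs <- utils::combn(EVENTS_LONG, 2, simplify = FALSE)
  for (p in pairs) for (e in p) add(hist_key(p), "acute", e)
  for (p in pairs) add(hist_key(p), "post_acute")
  shapes <- do.call(rbind, rows)
  alive <- rbind(cbind(shapes, tx = "on"), cbind(shapes, tx = "off"))
  st <- rbind(alive,
              data.frame(history = "", phase = "dead",
                         acute_event = NA_character_, tx = NA_character_))
  st$id <- seq_len(nrow(st))
  st$name <- ifelse(
    st$phase == "dead", "dead",
    paste0(ifelse(st$phase == "event_free", "event_free",
                  paste0(st$history, ":",
                         ifelse(st$phase == "acute",
                                paste0("acute_", st$acute_event),
                                "post"))),
           "|", st$tx))
  st <- st[, c("id", "name", "history", "phase", "acute_event", "tx")]
  class(st) <- c("state_space", "data.frame")
  st
}

state_history_list <- function(states) {
  strsplit(states$history, "+", fixed = TRUE)
}

#' Hazard multiplier from event history
#'
#' Product over prior events in the history of the published
#' subsequent-event hazard ratios HR(prior -> future); an empty history
#' gives 1. Future MI carries HR 1.00 from every prior event. After two
#' concomitant events only those same events are permitted as future
#' events.
#'
#' @param history Character vector of prior long-term events (possibly
#'   empty).
#' @param future_event The candidate future event.
#' @param subsequent_hr 4x4 matrix of HRs, rows = prior, cols = future.
#' @return Hazard multiplier (> 0).
#' @export
history_multiplier <- function(history, future_event, subsequent_hr) {
  history <- history[nzchar(history)]
  if (length(history) == 0) return(1)
  if (length(history) >= 2 && !(future_event %in% history)) {
    stop("event ", future_event, " not permitted with history {",
         paste(history, collapse = ", "), "}")
  }
  prod(subsequent_hr[history, future_event])
}

#' Aging hazard multiplier
#'
#' The per-decade hazard ratio is applied continuously from the reference
#' age (cohort age at month 6) as `HR^((age_now - reference_age)/10)`;
#' cycles within the first 6 months return 1 because trial rates already
#' reflect that period.
#'
#' @param event Event code (OMB, MI, IS, ICH; others return 1).
#' @param age_now Current cohort age in years.
#' @param reference_age Cohort age at month 6.
#' @param aging_hr Named vector of per-decade HRs.
#' @return Hazard multiplier.
#' @export
aging_multiplier <- function(event, age_now, reference_age, aging_hr) {
  if (age_now <= reference_age) return(1)
  hr <- aging_hr[event]
  if (is.na(hr)) return(1)
  unname(hr^((age_now - reference_age) / 10))
}

#' Case fatality probability of a long-term event
#'
#' Returns the case-fatality rate of the age band matching the current
#' age; ages below the lowest band clamp to the lowest band. All published
#' intervals (30 or 90 days) fit within one 3-month cycle, so the CFR is
#' applied once, in the acute cycle.
#'
#' @param event Long-term event code.
#' @param age Age in years.
#' @param fatality Fatality table (`event`, `age_lo`, `age_hi`,
#'   `interval_days`, `cfr`).
#' @return Death probability in \[0, 1\].
#' @export
event_fatality <- function(event, age, fatality) {
  b <- fatality[fatality$event == event, ]
  if (nrow(b) == 0) stop("no fatality rows for event ", event)
  b <- b[order(b$age_lo), ]
  age <- max(age, b$age_lo[1])
  i <- findInterval(age, b$age_lo)
  b$cfr[i]
}

#' Per-cycle background death probability
#'
#' The annual general-population death probability is converted to the
#' hazard scale, multiplied by the state-specific excess-mortality hazard
#' ratio, and pro-rated to the cycle:
#' `1 - (1 - qx)^(cycle_length * hr)`.
#'
#' @param qx Annual death probability in \[0, 1\].
#' @param state_hr Excess-mortality hazard ratio (> 0).
#' @param cycle_length_years Cycle length in years (default 0.25).
#' @return Per-cycle death probability.
#' @export
background_death_prob <- function(qx, state_hr, cycle_length_years = 0.25) {
  if (any(state_hr <= 0)) stop("state_hr must be > 0")
  1 - (1 - qx)^(cycle_length_years * state_hr)
}

#' Competing-risk rate-to-probability conversion
#'
#' Converts per-100-patient-year event rates for competing destinations to
#' per-cycle probabilities:
#' `p_i = (r_i / sum(r)) * (1 - exp(-sum(r) * t))` with rates in
#' per-person-year units, plus the complementary stay probability.
#'
#' @param rates Non-negative rates per 100 patient-years (named by event).
#' @param cycle_length_years Cycle length in years.
#' @return List with `p` (per-event probabilities) and `stay`.
#' @export
rate_to_competing_probs <- function(rates, cycle_length_years = 0.25) {
  if (any(rates < 0)) stop("rates must be non-negative")
  r <- rates / 100
  tot <- sum(r)
  if (tot == 0) {
    return(list(p = rates * 0, stay = 1))
  }
  p_any <- 1 - exp(-tot * cycle_length_years)
  p <- r / tot * p_any
  list(p = p, stay = 1 - sum(p))
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", nrow(x), " states (",
      sum(x$tx == "on", na.rm = TRUE), " on-treatment, ",
      sum(x$tx == "off", na.rm = TRUE), " off-treatment, 1 dead)\n",
      sep = "")
  invisible(x)
}

# Static per-state structures used by the transition engine: history
# multipliers, permitted events, destination indices, off-treatment twins,
# no-event successors and excess-mortality HRs.
state_statics <- function(config, states = enumerate_states()) {
  n <- nrow(states)
  hist <- state_history_list(states)
  alive <- states$phase != "dead"
  dead_id <- states$id[states$phase == "dead"]

  hist_mult <- matrix(0, n, 4, dimnames = list(NULL, EVENTS_LONG))
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
      hist_mult[i, e] <- history_multiplier(h, e, config$subsequent_hr)
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

  # Excess mortality vs the general population: event-free carries the
  # prior-ACS/PCI HR; histories multiply per-event HRs (OMB contributes the
  # event-free value because no OMB-specific excess mortality is published).
  mhr <- config$mortality_hr
  mort_hr <- vapply(seq_len(n), function(i) {
    if (!alive[i]) return(1)
    h <- hist[[i]]
    if (length(h) == 0) return(unname(mhr["event_free"]))
    prod(mhr[h])
  }, numeric(1))

  list(states = states, n = n, alive = alive, dead_id = dead_id,
       hist_mult = hist_mult, allowed = allowed, dest = dest,
       off_twin = off_twin, next_no_event = next_no_event,
       mort_hr = mort_hr, is_acute = states$phase == "acute",
       is_on = !is.na(states$tx) & states$tx == "on")
}
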
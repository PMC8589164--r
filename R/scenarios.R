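#' Define a treatment-strategy scenario
#'
#' Three step-down strategies are supported: the base case starts on the
#' blended triple-or-dual regimen and switches to monotherapy at 6 months;
#' `"triple_dual_mono"` starts on triple therapy, steps down to dual at 3
#' months and to monotherapy between 6 and 9 months; `"dual_mono"` starts
#' on dual therapy and switches to monotherapy between 6 and 12 months.
#' Ranged switch times default to the latest value. Scenario toggles cover
#' the VKA agent unit cost (acenocoumarol vs warfarin), a shorter horizon,
#' a discount-rate override, and user-supplied event-related
#' discontinuation probabilities.
#'
#' @param strategy One of `"triple_or_dual_mono"`, `"triple_dual_mono"`,
#'   `"dual_mono"`.
#' @param switch_dual_months Month of the triple-to-dual step-down
#'   (strategy `"triple_dual_mono"` only).
#' @param switch_mono_months Month of the switch to monotherapy.
#' @param horizon_years Horizon in years, or `NULL` for lifetime.
#' @param perspective `"payer"` or `"societal"`.
#' @param vka_agent `"acenocoumarol"` (base case) or `"warfarin"`.
#' @param discount_rate_annual Optional discount override.
#' @param wtp Optional willingness-to-pay override.
#' @param event_discontinuation Optional named vector of per-event
#'   permanent discontinuation probabilities (hook for alternative
#'   sources).
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(strategy = "triple_or_dual_mono",
                          switch_dual_months = 3,
                          switch_mono_months = NULL,
                          horizon_years = NULL,
                          perspective = "payer",
                          vka_agent = "acenocoumarol",
                          discount_rate_annual = NULL,
                          wtp = NULL,
                          event_discontinuation = NULL) {
  strategy <- match.arg(strategy, c("triple_or_dual_mono",
                                    "triple_dual_mono", "dual_mono"))
  if (is.null(switch_mono_months)) {
    switch_mono_months <- switch(strategy,
      triple_or_dual_mono = 6, triple_dual_mono = 9, dual_mono = 12)
  }
  if (strategy == "triple_dual_mono" &&
      switch_dual_months >= switch_mono_months) {
    stop("step-down times must be increasing (triple -> dual -> mono)")
  }
  structure(list(strategy = strategy,
                 switch_dual_months = switch_dual_months,
                 switch_mono_months = switch_mono_months,
                 horizon_years = horizon_years,
                 perspective = perspective,
                 vka_agent = vka_agent,
                 discount_rate_annual = discount_rate_annual,
                 wtp = wtp,
                 event_discontinuation = event_discontinuation),
            class = "scenario_spec")
}

months_to_cycles <- function(months) {
  if (months %% 3 != 0) stop("switch timepoints must be multiples of 3 months")
  as.integer(months / 3)
}

#' Build a cycle-indexed strategy schedule
#'
#' Converts a scenario's step-down timepoints (months, at 3 months per
#' cycle) into contiguous phase blocks `[start, end)` that partition the
#' horizon. Phases only step down (triple, then dual, then monotherapy).
#'
#' @param spec A [scenario_spec()].
#' @param horizon Total number of cycles to cover.
#' @return A `strategy_schedule` data frame with columns `phase`, `start`,
#'   `end`.
#' @export
build_schedule <- function(spec, horizon) {
  mono_at <- months_to_cycles(spec$switch_mono_months)
  blocks <- switch(spec$strategy,
    triple_or_dual_mono = data.frame(
      phase = c("triple_or_dual", "mono"),
      start = c(0L, mono_at), end = c(mono_at, horizon)),
    triple_dual_mono = {
      dual_at <- months_to_cycles(spec$switch_dual_months)
      data.frame(phase = c("triple", "dual", "mono"),
                 start = c(0L, dual_at, mono_at),
                 end = c(dual_at, mono_at, horizon))
    },
    dual_mono = data.frame(phase = c("dual", "mono"),
                           start = c(0L, mono_at),
                           end = c(mono_at, horizon)))
  blocks <- blocks[blocks$start < blocks$end, ]
  if (blocks$start[1] != 0 || blocks$end[nrow(blocks)] != horizon ||
      (nrow(blocks) > 1 &&
       any(blocks$start[-1] != blocks$end[-nrow(blocks)]))) {
    stop("schedule must partition [0, horizon)")
  }
  class(blocks) <- c("strategy_schedule", "data.frame")
  blocks
}

apply_scenario_overrides <- function(config, spec) {
  if (!is.null(spec$vka_agent)) config$vka_agent <- spec$vka_agent
  if (!is.null(spec$discount_rate_annual)) {
    config$run$discount_rate_annual <- spec$discount_rate_annual
  }
  if (!is.null(spec$wtp)) config$run$wtp <- spec$wtp
  if (!is.null(spec$event_discontinuation)) {
    d <- config$discontinuation
    for (e in names(spec$event_discontinuation)) {
      d$prob[d$kind == "event" & d$key == e] <-
        spec$event_discontinuation[[e]]
    }
    config$discontinuation <- d
  }
  validate_model_config(config)
  config
}

#' Run one scenario
#'
#' Applies the scenario overrides to the configuration, builds the
#' strategy schedule, solves both arms, and computes incremental results
#' under both perspectives.
#'
#' @param config The base `model_config`.
#' @param spec A [scenario_spec()]; default is the base case.
#' @return List with `apixaban`, `vka`, `incremental_payer`,
#'   `incremental_societal`, `spec` and `schedule`.
#' @export
run_scenario <- function(config, spec = scenario_spec()) {
  config <- apply_scenario_overrides(config, spec)
  horizon <- if (is.null(spec$horizon_years)) horizon_cycles(config) else
    as.integer(ceiling(spec$horizon_years / config$run$cycle_length_years))
  schedule <- build_schedule(spec, horizon)
  out <- run_base_case(config, schedule = schedule, horizon = horizon)
  out$spec <- spec
  out$schedule <- schedule
  out
}
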
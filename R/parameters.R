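#' Path to the shipped parameter pack
#'
#' The package ships the full published input set (trial event rates,
#' hazard ratios, case-fatality rates, discontinuation probabilities, drug
#' and event costs, utilities, cohort demographics and run settings) as
#' plain-text files under `inst/extdata/paper_pack`.
#'
#' @return Directory path of the default parameter pack.
#' @export
default_pack_path <- function() {
  system.file("extdata", "paper_pack", package = "oaccea", mustWork = TRUE)
}

#' Path to the shipped synthetic Spain-like life table
#'
#' A Gompertz-generated period life table calibrated so that life
#' expectancy at birth is about 83 years (Spain-like). It is a synthetic
#' stand-in for the Spanish 2019 national life table, which is not
#' redistributed with the package; see [gompertz_life_table()].
#'
#' @return CSV file path with columns `age,qx`.
#' @export
default_life_table_path <- function() {
  system.file("extdata", "life_table_es2019_synthetic.csv",
              package = "oaccea", mustWork = TRUE)
}

#' Load a life table
#'
#' Reads a CSV with columns `age` (contiguous integer years) and `qx`
#' (annual death probability). `qx` is coerced to 1 at the terminal age,
#' with a warning if the stored value differs. Lookups below the youngest
#' age clamp to the first row; above the terminal age `qx` is 1.
#'
#' @param source CSV path, or a data frame with `age` and `qx` columns.
#' @param terminal_age Age at which `qx` is forced to 1 (default 100).
#' @return A `life_table` data frame.
#' @export
load_life_table <- function(source, terminal_age = 100) {
  lt <- if (is.data.frame(source)) source else utils::read.csv(source)
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table must have columns 'age' and 'qx'")
  }
  lt <- lt[order(lt$age), c("age", "qx")]
  if (any(diff(lt$age) != 1)) {
    stop("life table ages must be contiguous (gap found)")
  }
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life table qx outside [0, 1]")
  if (max(lt$age) < terminal_age) {
    stop("life table must extend to the terminal age ", terminal_age)
  }
  lt <- lt[lt$age <= terminal_age, ]
  iterm <- which(lt$age == terminal_age)
  if (lt$qx[iterm] != 1) {
    warning("qx at terminal age ", terminal_age, " coerced to 1 (was ",
            lt$qx[iterm], ")")
    lt$qx[iterm] <- 1
  }
  attr(lt, "terminal_age") <- terminal_age
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Annual death probability lookup with clamping
#'
#' @param life_table A [load_life_table()] table.
#' @param age Numeric age(s) in years; non-integer ages use the completed
#'   (floored) age.
#' @return Annual death probabilities.
#' @export
life_table_qx <- function(life_table, age) {
  a <- pmin(pmax(floor(age), min(life_table$age)), max(life_table$age))
  life_table$qx[match(a, life_table$age)]
}

#' Derive off-treatment event rates
#'
#' The published hazard ratios compare apixaban with no treatment, so
#' dividing the apixaban monotherapy rate by the HR recovers the untreated
#' rate. The same off-treatment rates apply to both arms.
#'
#' @param mono_rates Named vector of apixaban monotherapy rates per 100
#'   patient-years (names are event codes).
#' @param no_treatment_hr Named vector of apixaban-vs-no-treatment HRs.
#' @return Named vector of off-treatment rates per 100 patient-years.
#' @export
derive_no_treatment_rates <- function(mono_rates, no_treatment_hr) {
  ev <- names(mono_rates)
  hr <- no_treatment_hr[ev]
  if (any(is.na(hr))) stop("missing no-treatment HR for: ",
                           paste(ev[is.na(hr)], collapse = ", "))
  if (any(hr <= 0)) stop("no-treatment HR must be > 0")
  mono_rates / hr
}

#' Share-weighted P2Y12 inhibitor cost per cycle
#'
#' @param shares Named proportions (clopidogrel, prasugrel, ticagrelor)
#'   summing to 1.
#' @param costs_per_cycle Named per-cycle costs for the same agents.
#' @return Weighted cost in euro per 3-month cycle.
#' @export
weighted_p2y12_cost <- function(shares, costs_per_cycle) {
  if (abs(sum(shares) - 1) > 1e-9) {
    stop("p2y12 shares must sum to 1 (got ", sum(shares), ")")
  }
  if (any(shares < 0)) stop("p2y12 shares must be non-negative")
  sum(shares * costs_per_cycle[names(shares)])
}

read_pack_csv <- function(path, file) {
  f <- file.path(path, file)
  if (!file.exists(f)) stop("parameter pack file missing: ", file)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Load a parameter pack into a validated model configuration
#'
#' Reads the structured input files of a parameter pack directory (by
#' default the shipped published set), attaches a life table, derives the
#' secondary inputs (off-treatment event rates, share-weighted P2Y12 cost
#' per arm), and validates every invariant. The returned `model_config` is
#' the single source of truth for a model run.
#'
#' @param path Parameter pack directory (default [default_pack_path()]).
#' @param life_table A `life_table`, a CSV path, or `NULL` for the shipped
#'   synthetic Spain-like table.
#' @return A validated `model_config` object.
#' @export
load_parameter_pack <- function(path = default_pack_path(),
                                life_table = NULL) {
  settings <- jsonlite::read_json(file.path(path, "settings.json"),
                                  simplifyVector = TRUE)
  rates <- read_pack_csv(path, "event_rates.csv")
  hrs <- read_pack_csv(path, "hazard_ratios.csv")
  fatality <- read_pack_csv(path, "fatality.csv")
  fatality$age_hi <- as.numeric(fatality$age_hi)
  disc <- read_pack_csv(path, "discontinuation.csv")
  drugs <- read_pack_csv(path, "drug_costs.csv")
  p2y12 <- read_pack_csv(path, "p2y12_shares.csv")
  event_costs <- read_pack_csv(path, "event_costs.csv")
  utilities <- read_pack_csv(path, "utilities.csv")

  if (is.null(life_table)) life_table <- default_life_table_path()
  if (!inherits(life_table, "life_table")) {
    life_table <- load_life_table(life_table,
                                  terminal_age = settings$run$terminal_age)
  }

  hr_block <- function(block) {
    x <- hrs[hrs$block == block, ]
    stats::setNames(x$hr, x$event)
  }
  sub <- hrs[hrs$block == "subsequent", ]
  subsequent <- matrix(1, 4, 4, dimnames = list(prior = EVENTS_LONG,
                                                future = EVENTS_LONG))
  subsequent[cbind(sub$prior, sub$event)] <- sub$hr

  config <- structure(list(
    rates = rates,
    no_treatment_hr = hr_block("no_treatment"),
    aging_hr = hr_block("aging"),
    subsequent_hr = subsequent,
    mortality_hr = hr_block("postacute_mortality"),
    hr_ci = hrs[, c("block", "prior", "event", "hr", "lo", "hi")],
    fatality = fatality,
    discontinuation = disc,
    drugs = drugs,
    p2y12 = p2y12,
    event_costs = event_costs,
    utilities = utilities,
    cohort = as.list(settings$cohort),
    run = as.list(settings$run),
    monitoring = as.list(settings$monitoring),
    interruption_cycles = settings$discontinuation_interruption_cycles,
    vka_agent = settings$vka_agent,
    baseline_utility_coeffs = unlist(settings$baseline_utility_coeffs),
    psa = as.list(settings$psa),
    life_table = life_table
  ), class = "model_config")

  validate_model_config(config)
  config
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the input set: rates and standard
#' errors non-negative with all seven events present per (phase, arm);
#' hazard ratios positive with point estimates inside their confidence
#' intervals and the prior-MI column of the subsequent-event matrix
#' identically 1; case-fatality rates in \[0, 1\] with non-overlapping age
#' bands; probabilities in \[0, 1\]; costs non-negative; P2Y12 shares on
#' the simplex; utility ratios in (0, 1\]; cohort proportions in \[0, 1\];
#' cycle_days = 365.25 x cycle_length_years.
#'
#' @param config A `model_config`.
#' @return `config`, invisibly; errors name the offending field.
#' @export
validate_model_config <- function(config) {
  fail <- function(...) stop("model_config validation: ", ..., call. = FALSE)
  r <- config$rates
  if (any(r$rate < 0)) fail("rates: negative event rate")
  if (any(r$se < 0)) fail("rates: negative standard error")
  combos <- expand.grid(phase = PHASES_TX, arm = ARMS,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    ev <- r$event[r$phase == combos$phase[i] & r$arm == combos$arm[i]]
    if (!setequal(ev, EVENTS_ALL) || length(ev) != 7) {
      fail("rates: (", combos$phase[i], ", ", combos$arm[i],
           ") must list all 7 events exactly once")
    }
  }
  hrs <- c(config$no_treatment_hr, config$aging_hr, config$mortality_hr,
           as.vector(config$subsequent_hr))
  if (any(hrs <= 0)) fail("hazard ratios must be > 0")
  if (any(config$subsequent_hr["MI", ] != 1)) {
    fail("subsequent_hr: prior-MI column must be identically 1.00")
  }
  ci <- config$hr_ci
  ok <- is.na(ci$lo) | (ci$lo <= ci$hr & ci$hr <= ci$hi)
  if (!all(ok)) fail("hazard ratio outside its CI: ",
                     paste(ci$event[!ok], collapse = ", "))
  ft <- config$fatality
  if (any(ft$cfr < 0 | ft$cfr > 1)) fail("fatality: cfr outside [0, 1]")
  if (!all(ft$interval_days %in% c(30, 90))) {
    fail("fatality: interval_days must be 30 or 90")
  }
  for (e in unique(ft$event)) {
    b <- ft[ft$event == e, ]
    b <- b[order(b$age_lo), ]
    if (nrow(b) > 1 && any(b$age_lo[-1] < b$age_hi[-nrow(b)])) {
      fail("fatality: overlapping age bands for ", e)
    }
  }
  d <- config$discontinuation
  pr <- d$prob
  if (any(pr < 0 | pr > 1)) fail("discontinuation: probability outside [0, 1]")
  if (config$interruption_cycles < 0) {
    fail("interruption_cycles must be non-negative")
  }
  if (any(config$drugs$cost_per_cycle < 0) ||
      any(config$drugs$price_per_mg < 0)) fail("drugs: negative cost")
  for (i in seq_len(nrow(config$p2y12))) {
    s <- unlist(config$p2y12[i, c("clopidogrel", "prasugrel", "ticagrelor")])
    if (abs(sum(s) - 1) > 1e-9) {
      fail("p2y12 shares for arm '", config$p2y12$arm[i],
           "' must sum to 1 (got ", sum(s), ")")
    }
  }
  ec <- config$event_costs
  if (any(unlist(ec[, -1]) < 0)) fail("event_costs: negative cost")
  if (config$monitoring$inr_cost_per_test < 0 ||
      config$monitoring$inr_tests_per_cycle < 0) {
    fail("monitoring: negative cost or frequency")
  }
  ut <- config$utilities
  if (any(ut$ratio <= 0 | ut$ratio > 1)) {
    fail("utilities: ratio outside (0, 1]")
  }
  ch <- config$cohort
  if (ch$start_age <= 0) fail("cohort: start_age must be > 0")
  props <- c(ch$male_share, ch$initial_postacute_mi_share)
  if (any(props < 0 | props > 1)) fail("cohort: proportion outside [0, 1]")
  bu <- baseline_utility(ch$start_age, ch$male_share,
                         config$baseline_utility_coeffs)
  if (bu <= 0 || bu >= 1) fail("baseline utility at cohort age outside (0, 1)")
  rn <- config$run
  if (rn$discount_rate_annual < 0) fail("run: discount rate must be >= 0")
  if (abs(rn$cycle_days - 365.25 * rn$cycle_length_years) > 1e-9) {
    fail("run: cycle_days must equal 365.25 x cycle_length_years")
  }
  if (rn$triple_share_in_blend < 0 || rn$triple_share_in_blend > 1) {
    fail("run: triple_share_in_blend outside [0, 1]")
  }
  if (horizon_cycles(config) < 1) fail("run: horizon must be >= 1 cycle")
  invisible(config)
}

#' Number of cycles in the lifetime horizon
#'
#' Cycles from the cohort start age up to the terminal age (100 years by
#' default), `ceiling((terminal_age - start_age) / cycle_length)`.
#'
#' @param config A `model_config`.
#' @return Integer cycle count.
#' @export
horizon_cycles <- function(config) {
  as.integer(ceiling((config$run$terminal_age - config$cohort$start_age) /
                       config$run$cycle_length_years))
}

#' Event rates for a (phase, arm) pair
#'
#' `phase = "off"` returns the derived off-treatment rates (identical for
#' both arms).
#'
#' @param config A `model_config`.
#' @param phase One of `"triple_or_dual"`, `"triple"`, `"dual"`, `"mono"`,
#'   `"off"`.
#' @param arm `"apixaban"` or `"vka"`.
#' @return Named vector of rates per 100 patient-years for all 7 events.
#' @export
event_rates <- function(config, phase, arm) {
  if (phase == "off") {
    mono <- event_rates(config, "mono", "apixaban")
    return(derive_no_treatment_rates(mono, config$no_treatment_hr))
  }
  r <- config$rates[config$rates$phase == phase & config$rates$arm == arm, ]
  stats::setNames(r$rate, r$event)[EVENTS_ALL]
}

#' Per-cycle drug acquisition cost of one agent
#' @param config A `model_config`.
#' @param agent Agent name as in the drug cost table.
#' @return Euro per 3-month cycle.
#' @export
drug_cost_per_cycle <- function(config, agent) {
  i <- match(agent, config$drugs$agent)
  if (is.na(i)) stop("unknown agent: ", agent)
  config$drugs$cost_per_cycle[i]
}

p2y12_shares_arm <- function(config, arm) {
  i <- match(arm, config$p2y12$arm)
  unlist(config$p2y12[i, c("clopidogrel", "prasugrel", "ticagrelor")])
}

#' Per-cycle regimen drug cost for a treatment phase
#'
#' Monotherapy costs the oral anticoagulant alone; dual therapy adds the
#' share-weighted P2Y12 inhibitor; triple therapy also adds aspirin. The
#' blended "triple or dual" phase adds aspirin for the triple share of the
#' cohort only (the blend affects drug cost, not event rates).
#'
#' @param config A `model_config`.
#' @param phase Treatment phase.
#' @param arm `"apixaban"` or `"vka"`.
#' @return Euro per cycle per on-treatment patient.
#' @export
regimen_cost_per_cycle <- function(config, phase, arm) {
  oac <- if (arm == "apixaban") "apixaban" else config$vka_agent
  cost <- drug_cost_per_cycle(config, oac)
  if (phase == "mono") return(cost)
  p2y <- weighted_p2y12_cost(
    p2y12_shares_arm(config, arm),
    stats::setNames(config$drugs$cost_per_cycle, config$drugs$agent))
  asp <- drug_cost_per_cycle(config, "aspirin")
  cost + p2y + switch(phase,
    dual = 0,
    triple = asp,
    triple_or_dual = config$run$triple_share_in_blend * asp,
    stop("unknown phase: ", phase))
}

#' Write / read a model configuration
#'
#' Round-trip serialization to JSON at full floating-point precision; a
#' re-loaded configuration is field-identical to the original.
#'
#' @param config A `model_config`.
#' @param path File path (`.json`).
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns the validated `model_config`.
#' @export
write_model_config <- function(config, path) {
  x <- unclass(config)
  # named vectors serialize as JSON objects, not bare arrays
  for (f in c("no_treatment_hr", "aging_hr", "mortality_hr",
              "baseline_utility_coeffs")) {
    x[[f]] <- as.list(x[[f]])
  }
  x$life_table <- as.data.frame(x$life_table)
  # JSON has no Inf: open-ended age bands travel as strings
  x$fatality$age_hi <- as.character(x$fatality$age_hi)
  x$.terminal_age <- attr(config$life_table, "terminal_age")
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  term <- x$.terminal_age
  x$.terminal_age <- NULL
  x$no_treatment_hr <- unlist(x$no_treatment_hr)
  x$aging_hr <- unlist(x$aging_hr)
  x$mortality_hr <- unlist(x$mortality_hr)
  x$baseline_utility_coeffs <- unlist(x$baseline_utility_coeffs)
  x$subsequent_hr <- matrix(unlist(x$subsequent_hr), 4, 4,
                            dimnames = list(prior = EVENTS_LONG,
                                            future = EVENTS_LONG))
  x$fatality$age_hi <- as.numeric(x$fatality$age_hi)
  lt <- x$life_table
  attr(lt, "terminal_age") <- term
  class(lt) <- c("life_table", "data.frame")
  x$life_table <- lt
  config <- structure(x, class = "model_config")
  validate_model_config(config)
  config
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat("  cohort: start age", x$cohort$start_age, "| male share",
      x$cohort$male_share, "| initial post-MI",
      x$cohort$initial_postacute_mi_share, "\n")
  cat("  run: ", horizon_cycles(x), " cycles of ",
      x$run$cycle_length_years, " y, discount ",
      x$run$discount_rate_annual * 100, "%/y, WTP EUR ", x$run$wtp,
      "/QALY\n", sep = "")
  cat("  VKA agent:", x$vka_agent, "| perspective:", x$run$perspective, "\n")
  invisible(x)
}
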
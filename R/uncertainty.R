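# One-way deterministic sensitivity analysis (DSA) and probabilistic
# sensitivity analysis (PSA) over the full parameter registry.

se_unprinted <- function(m, rel_ci = 0.10) abs(m) * rel_ci / 1.96

ratio_se <- function(ratio, me, se_e, mc, se_c) {
  ratio * sqrt((se_e / me)^2 + (se_c / mc)^2)
}

#' Sensitivity-analysis parameter registry
#'
#' Enumerates every input varied in DSA/PSA with its sampling distribution
#' (gamma for rates and costs, beta for probabilities and utility ratios,
#' lognormal for hazard ratios, truncated normal for age) and its one-way
#' bounds: the printed 95% CI when available, otherwise mean +/- 1.96
#' standard errors, otherwise +/- 10% of the base value. Hazard ratios
#' assumed equal to another event's (CRNMB/REV/SE off-treatment HRs, the
#' OMB excess-mortality HR) are tied to their source parameter rather than
#' listed separately. P2Y12 shares are sampled from a Dirichlet
#' distribution in PSA and are not varied one-way.
#'
#' @param config A `model_config`.
#' @return Data frame with columns `id`, `dist`, `mean`, `se`, `low`,
#'   `high`, `source`.
#' @export
psa_registry <- function(config) {
  rows <- list()
  add <- function(id, dist, mean, se = NA_real_, lo = NA_real_,
                  hi = NA_real_) {
    if (!is.na(lo)) src <- "ci"
    else if (!is.na(se)) src <- "se"
    else src <- "pct10"
    if (is.na(se)) se <- se_unprinted(mean, config$psa$unprinted_rel_ci)
    if (is.na(lo)) {
      if (src == "se") {
        lo <- mean - 1.96 * se
        hi <- mean + 1.96 * se
      } else {
        lo <- 0.9 * mean
        hi <- 1.1 * mean
      }
    }
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, dist = dist, mean = mean, se = se, low = lo, high = hi,
      source = src, stringsAsFactors = FALSE)
  }

  r <- config$rates
  for (i in seq_len(nrow(r))) {
    add(paste("rate", r$phase[i], r$arm[i], r$event[i], sep = "|"),
        "gamma", r$rate[i], se = r$se[i])
  }
  ci <- config$hr_ci
  hrci <- function(block, event, prior = NA) {
    j <- ci$block == block & ci$event == event &
      (is.na(prior) | ci$prior %in% prior)
    c(ci$lo[which(j)[1]], ci$hi[which(j)[1]])
  }
  for (e in EVENTS_LONG) {
    b <- hrci("no_treatment", e)
    add(paste0("hr_no_treatment|", e), "lognormal",
        config$no_treatment_hr[e], lo = b[1], hi = b[2])
    b <- hrci("aging", e)
    add(paste0("hr_aging|", e), "lognormal", config$aging_hr[e],
        lo = b[1], hi = b[2])
  }
  sub <- ci[ci$block == "subsequent" & !is.na(ci$lo), ]
  for (i in seq_len(nrow(sub))) {
    add(paste("hr_subsequent", sub$prior[i], sub$event[i], sep = "|"),
        "lognormal", sub$hr[i], lo = sub$lo[i], hi = sub$hi[i])
  }
  for (k in c("event_free", "MI", "IS", "ICH")) {
    b <- hrci("postacute_mortality", k)
    add(paste0("hr_mortality|", k), "lognormal", config$mortality_hr[k],
        lo = b[1], hi = b[2])
  }
  ft <- config$fatality
  for (i in seq_len(nrow(ft))) {
    add(paste("cfr", ft$event[i], ft$age_lo[i], sep = "|"), "beta",
        ft$cfr[i])
  }
  d <- config$discontinuation
  for (i in which(d$kind == "event" & d$prob > 0)) {
    add(paste0("disc_event|", d$key[i]), "beta", d$prob[i], se = d$se[i])
  }
  for (i in which(d$kind == "unrelated")) {
    add(paste0("disc_unrelated|", d$key[i]), "beta", d$prob[i],
        se = d$se[i])
  }
  dr <- config$drugs
  for (i in seq_len(nrow(dr))) {
    add(paste0("cost_drug|", dr$agent[i]), "gamma", dr$cost_per_cycle[i])
  }
  ec <- config$event_costs
  for (i in seq_len(nrow(ec))) {
    add(paste0("cost_acute|", ec$event[i]), "gamma", ec$acute[i])
    if (ec$maintenance_monthly[i] > 0) {
      add(paste0("cost_maint|", ec$event[i]), "gamma",
          ec$maintenance_monthly[i])
    }
    if (ec$societal_acute[i] > 0) {
      add(paste0("cost_soc_acute|", ec$event[i]), "gamma",
          ec$societal_acute[i])
    }
    if (ec$societal_monthly[i] > 0) {
      add(paste0("cost_soc_maint|", ec$event[i]), "gamma",
          ec$societal_monthly[i])
    }
  }
  add("cost_inr", "gamma", config$monitoring$inr_cost_per_test)
  ut <- config$utilities
  for (i in seq_len(nrow(ut))) {
    tag <- if (ut$period[i] == "acute") "util_acute" else "util_post"
    add(paste(tag, ut$event[i], sep = "|"), "beta", ut$ratio[i],
        se = ratio_se(ut$ratio[i], ut$mean_event[i], ut$se_event[i],
                      ut$mean_control[i], ut$se_control[i]))
  }
  add("age", "normal", config$cohort$start_age,
      se = config$cohort$start_age_se)
  p <- config$cohort$male_share
  add("male_share", "beta", p,
      se = sqrt(p * (1 - p) / config$cohort$cohort_n))
  do.call(rbind, rows)
}

#' One-way bounds for a registered parameter
#'
#' @param parameter Registry id (see [psa_registry()]).
#' @param config A `model_config`.
#' @return List with `low`, `high`, `base` and `source` (`ci`, `se` or
#'   `pct10`).
#' @export
dsa_bounds <- function(parameter, config) {
  reg <- psa_registry(config)
  i <- match(parameter, reg$id)
  if (is.na(i)) stop("unknown parameter id: ", parameter)
  list(low = reg$low[i], high = reg$high[i], base = reg$mean[i],
       source = reg$source[i])
}

# Writes one registry parameter back into the configuration. Tied
# parameters (short-term off-treatment HRs, the OMB mortality HR) are
# updated together with their source.
config_set <- function(config, id, value) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind == "rate") {
    j <- config$rates$phase == parts[2] & config$rates$arm == parts[3] &
      config$rates$event == parts[4]
    config$rates$rate[j] <- value
  } else if (kind == "hr_no_treatment") {
    e <- parts[2]
    tied <- c(OMB = "CRNMB", MI = "REV", IS = "SE")
    config$no_treatment_hr[e] <- value
    if (e %in% names(tied)) config$no_treatment_hr[tied[e]] <- value
  } else if (kind == "hr_aging") {
    config$aging_hr[parts[2]] <- value
  } else if (kind == "hr_subsequent") {
    config$subsequent_hr[parts[2], parts[3]] <- value
  } else if (kind == "hr_mortality") {
    config$mortality_hr[parts[2]] <- value
    if (parts[2] == "event_free") config$mortality_hr["OMB"] <- value
  } else if (kind == "cfr") {
    j <- config$fatality$event == parts[2] &
      config$fatality$age_lo == as.numeric(parts[3])
    config$fatality$cfr[j] <- value
  } else if (kind == "disc_event") {
    j <- config$discontinuation$kind == "event" &
      config$discontinuation$key == parts[2]
    config$discontinuation$prob[j] <- value
  } else if (kind == "disc_unrelated") {
    j <- config$discontinuation$kind == "unrelated" &
      config$discontinuation$key == parts[2]
    config$discontinuation$prob[j] <- value
  } else if (kind == "cost_drug") {
    config$drugs$cost_per_cycle[config$drugs$agent == parts[2]] <- value
  } else if (kind == "cost_acute") {
    config$event_costs$acute[config$event_costs$event == parts[2]] <- value
  } else if (kind == "cost_maint") {
    config$event_costs$maintenance_monthly[
      config$event_costs$event == parts[2]] <- value
  } else if (kind == "cost_soc_acute") {
    config$event_costs$societal_acute[
      config$event_costs$event == parts[2]] <- value
  } else if (kind == "cost_soc_maint") {
    config$event_costs$societal_monthly[
      config$event_costs$event == parts[2]] <- value
  } else if (kind == "cost_inr") {
    config$monitoring$inr_cost_per_test <- value
  } else if (kind == "util_acute") {
    j <- config$utilities$period == "acute" &
      config$utilities$event == parts[2]
    config$utilities$ratio[j] <- value
  } else if (kind == "util_post") {
    j <- config$utilities$period == "post_acute" &
      config$utilities$event == parts[2]
    config$utilities$ratio[j] <- value
  } else if (kind == "age") {
    config$cohort$start_age <- value
  } else if (kind == "male_share") {
    config$cohort$male_share <- value
  } else {
    stop("unknown parameter id: ", id)
  }
  config
}

#' One-way deterministic sensitivity analysis with tornado ranking
#'
#' Re-solves the model with each registered parameter at its lower and
#' upper bound (all other inputs at base case) and reports the
#' payer-perspective INMB, incremental QALYs and incremental costs at each
#' bound, sorted by absolute INMB swing.
#'
#' @param config A `model_config`.
#' @param parameters Registry ids to vary (default: the full registry).
#' @param wtp Willingness-to-pay for the INMB (default from config).
#' @param top Keep only the `top` largest swings (`NULL` = all).
#' @return A `dsa_results` data frame.
#' @export
run_dsa <- function(config, parameters = NULL, wtp = NULL, top = NULL) {
  reg <- psa_registry(config)
  if (is.null(parameters)) parameters <- reg$id
  if (is.null(wtp)) wtp <- config$run$wtp
  one <- function(id, value) {
    cfg <- config_set(config, id, value)
    res <- run_base_case(cfg)
    inc <- incremental(res$apixaban, res$vka, wtp, "payer")
    c(inmb = inc$inmb, dqaly = inc$delta_qaly, dcost = inc$delta_cost)
  }
  out <- lapply(parameters, function(id) {
    i <- match(id, reg$id)
    if (is.na(i)) stop("unknown parameter id: ", id)
    lo <- one(id, reg$low[i])
    hi <- one(id, reg$high[i])
    data.frame(id = id, low = reg$low[i], high = reg$high[i],
               inmb_low = lo["inmb"], inmb_high = hi["inmb"],
               dqaly_low = lo["dqaly"], dqaly_high = hi["dqaly"],
               dcost_low = lo["dcost"], dcost_high = hi["dcost"],
               swing = abs(hi["inmb"] - lo["inmb"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(-out$swing), ]
  if (!is.null(top)) out <- utils::head(out, top)
  class(out) <- c("dsa_results", "data.frame")
  out
}

sample_one <- function(dist, m, se, lo, hi, trunc = NULL) {
  if (dist == "lognormal") {
    if (is.na(lo) || is.na(hi) || lo <= 0 || lo == hi) return(m)
    sigma <- (log(hi) - log(lo)) / 3.92
    return(stats::rlnorm(1, meanlog = log(m), sdlog = sigma))
  }
  if (is.na(se) || se == 0 || m == 0) return(m)
  if (dist == "gamma") {
    v <- se^2
    return(stats::rgamma(1, shape = m^2 / v, rate = m / v))
  }
  if (dist == "beta") {
    v <- se^2
    if (v >= m * (1 - m)) {
      warning("beta variance too large for mean ", m, "; using mean")
      return(m)
    }
    a <- m * (m * (1 - m) / v - 1)
    return(stats::rbeta(1, a, a * (1 - m) / m))
  }
  if (dist == "normal") {
    repeat {
      x <- stats::rnorm(1, m, se)
      if (is.null(trunc) || (x >= trunc[1] && x <= trunc[2])) return(x)
    }
  }
  stop("unknown distribution: ", dist)
}

rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  g / sum(g)
}

#' Draw one probabilistic-sensitivity-analysis configuration
#'
#' Samples every registered parameter from its distribution (gamma via
#' moment matching for rates and costs, beta via moment matching for
#' probabilities and utility ratios, lognormal for hazard ratios with
#' `sigma = (log U - log L)/3.92`, truncated normal for age) plus a
#' Dirichlet draw of each arm's P2Y12 shares (concentration = shares times
#' the effective trial count), writes them into a copy of the
#' configuration and re-validates it. Uses the current RNG state; seed the
#' generator for reproducibility.
#'
#' @param config The base `model_config`.
#' @param registry Optional precomputed [psa_registry()].
#' @return List with `config` (the sampled, validated `model_config`) and
#'   `params` (named vector of sampled registry values).
#' @export
draw_psa_config <- function(config, registry = NULL) {
  if (is.null(registry)) registry <- psa_registry(config)
  trunc_age <- unlist(config$psa$age_truncation)
  sampled <- numeric(nrow(registry))
  cfg <- config
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    x <- sample_one(r$dist, r$mean, r$se, r$low, r$high,
                    trunc = if (r$id == "age") trunc_age else NULL)
    if (r$dist == "beta") x <- min(max(x, 0), 1)
    if (r$dist %in% c("gamma", "lognormal")) x <- max(x, 0)
    sampled[i] <- x
    cfg <- config_set(cfg, r$id, x)
  }
  names(sampled) <- registry$id
  nd <- cfg$psa$dirichlet_n
  for (a in seq_len(nrow(cfg$p2y12))) {
    shares <- unlist(cfg$p2y12[a, c("clopidogrel", "prasugrel",
                                    "ticagrelor")])
    cfg$p2y12[a, c("clopidogrel", "prasugrel", "ticagrelor")] <-
      as.list(rdirichlet1(shares * nd))
  }
  validate_model_config(cfg)
  list(config = cfg, params = sampled)
}

#' Probabilistic sensitivity analysis
#'
#' Repeats the model with jointly sampled inputs and records per-draw
#' incremental costs (payer and societal), life years, QALYs and INMB.
#' Reproducible given `seed`.
#'
#' @param config The base `model_config`.
#' @param n Number of draws (the published analysis uses 1,000).
#' @param seed Integer RNG seed.
#' @param keep_params Keep the matrix of sampled parameter values.
#' @return A `psa_results` object with element `draws` (data frame) and a
#'   `summary()` reporting cost-effectiveness-plane quadrant shares, mean
#'   increments and the share of draws cost-effective at the WTP.
#' @export
run_psa <- function(config, n = 1000, seed = NULL, keep_params = FALSE) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  registry <- psa_registry(config)
  draws <- vector("list", n)
  params <- if (keep_params) matrix(NA_real_, n, nrow(registry),
                                    dimnames = list(NULL, registry$id))
  for (i in seq_len(n)) {
    d <- draw_psa_config(config, registry)
    if (keep_params) params[i, ] <- d$params
    res <- run_base_case(d$config)
    ip <- res$incremental_payer
    is_ <- res$incremental_societal
    draws[[i]] <- data.frame(
      draw = i, delta_cost = ip$delta_cost,
      delta_cost_societal = is_$delta_cost,
      delta_ly = ip$delta_ly, delta_qaly = ip$delta_qaly,
      inmb = ip$inmb)
  }
  structure(list(draws = do.call(rbind, draws), n = n, seed = seed,
                 wtp = config$run$wtp, params = params),
            class = "psa_results")
}

#' @export
summary.psa_results <- function(object, wtp = NULL, ...) {
  d <- object$draws
  if (is.null(wtp)) wtp <- object$wtp
  quad <- c(
    SE = mean(d$delta_qaly > 0 & d$delta_cost < 0),
    NE = mean(d$delta_qaly > 0 & d$delta_cost >= 0),
    NW = mean(d$delta_qaly <= 0 & d$delta_cost >= 0),
    SW = mean(d$delta_qaly <= 0 & d$delta_cost < 0))
  ne_below <- mean(d$delta_qaly > 0 & d$delta_cost >= 0 &
                     d$delta_cost / d$delta_qaly <= wtp)
  list(quadrant_share = quad,
       share_cost_effective = unname(quad["SE"] + ne_below),
       mean_delta_cost = mean(d$delta_cost),
       mean_delta_ly = mean(d$delta_ly),
       mean_delta_qaly = mean(d$delta_qaly),
       mean_inmb = mean(wtp * d$delta_qaly - d$delta_cost),
       wtp = wtp, n = object$n)
}

#' @export
print.psa_results <- function(x, ...) {
  s <- summary(x)
  cat("<psa_results>", x$n, "draws\n")
  cat(sprintf("  SE quadrant (dominant): %.1f%% | cost-effective at WTP %d: %.1f%%\n",
              100 * s$quadrant_share["SE"], s$wtp,
              100 * s$share_cost_effective))
  cat(sprintf("  mean dCost EUR %.0f | mean dQALY %.3f\n",
              s$mean_delta_cost, s$mean_delta_qaly))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive incremental net monetary benefit for apixaban (ties count
#' one half).
#'
#' @param psa A [run_psa()] result (or its `draws` data frame).
#' @param wtp_grid Non-empty numeric vector of WTP thresholds.
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  if (length(wtp_grid) == 0) stop("wtp_grid must be non-empty")
  d <- if (inherits(psa, "psa_results")) psa$draws else psa
  if (nrow(d) == 0) stop("no PSA draws")
  prob <- vapply(wtp_grid, function(w) {
    nmb <- w * d$delta_qaly - d$delta_cost
    mean((nmb > 0) + 0.5 * (nmb == 0))
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}
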
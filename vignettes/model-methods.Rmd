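---
title: "Model and methods: apixaban versus VKA after ACS/PCI in atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaccea)
```

## The decision problem

Patients with non-valvular atrial fibrillation who have a recent acute
coronary syndrome (ACS) and/or undergo percutaneous coronary intervention
(PCI) need an oral anticoagulant (OAC) on top of antiplatelet therapy.
Trial evidence shows that an apixaban-based regimen bleeds less than a
vitamin-K-antagonist (VKA)-based regimen at similar ischemic risk, but
apixaban costs far more per day than acenocoumarol. `oaccea` weighs these
against each other over a lifetime from the Spanish payer and societal
perspectives, as a Markov cohort model with 3-month cycles.

## Health states

Long-term events are myocardial infarction (MI), ischemic stroke (IS),
intracranial hemorrhage (ICH) and other major bleeds (OMB). A patient's
clinical history is a set of at most two of these. Each incident event
occupies an *acute* state for exactly one cycle and then moves to the
chronic *post-acute* state for that history. After two concomitant events
only those same two events can recur; a recurrence re-enters the existing
acute state for that history. Crossing the 27 alive history/phase shapes
with treatment status (on/off) and adding the absorbing dead state yields
55 states (`enumerate_states()`).

Clinically relevant non-major bleeding (CRNMB), urgent revascularization
(REV) and systemic embolism (SE) are short-term events: they never change
state and instead accrue a one-cycle cost and a one-cycle utility
decrement in proportion to their per-cycle probability ("intensity").

The cohort starts at mean age 69.9 (71% male), 61.2% in the post-acute MI
state and the rest event-free, all on treatment.

## Hazards and transition probabilities

Event rates (per 100 patient-years) are phase-specific: blended
triple-or-dual, triple and dual therapy rates from the 6-month trial of
apixaban versus VKA in this population; monotherapy rates from long-term
anticoagulation trial data; off-treatment rates derived by dividing
apixaban monotherapy rates by the apixaban-versus-no-treatment hazard
ratios (so off-treatment rates are identical in both arms). Three
multiplicative adjustments apply to the four long-term event hazards:

* **Aging**: a per-decade hazard ratio applied as
  `HR^((age - reference_age)/10)` from month 6 onward (the trial period
  already embeds the first six months).
* **History**: the product over prior events of the published
  subsequent-event hazard ratios; prior or future MI carries HR 1.00.
* **Permission**: with two prior events, hazards of other events are
  zeroed.

Scaled hazards are converted to per-cycle probabilities with the standard
competing-risk formula `p_i = (r_i/sum r)(1 - exp(-sum r * t))`. Death is
a separate, independent cause: incident events carry an age-banded case
fatality probability applied once in the acute cycle, and every alive
state carries background mortality
`1 - (1 - qx)^(0.25 * HR_state)`, where `qx` comes from the life table
and `HR_state` is the excess-mortality hazard ratio of the state (1.16
for event-free — the cohort has prior ACS/PCI — and published values for
MI/IS/ICH histories). Death probabilities combine across causes as
`1 - prod(1 - p_k)`.

Two open structural choices are made explicit here. First, in joint
(two-event) states both the subsequent-event and the excess-mortality
hazard ratios combine **multiplicatively** (proportional-hazards
independence); no interaction estimates exist to support anything richer.
Second, OMB has no published excess-mortality hazard ratio, so an OMB
history contributes the event-free value 1.16 — a conservative floor.

## Treatment strategies, discontinuation, interruption

Strategies step down at fixed timepoints and never step up: the base case
runs the blended triple-or-dual regimen for 6 months and monotherapy
thereafter; alternatives start on triple (stepping to dual at 3 months
and monotherapy at 6–9) or dual (monotherapy at 6–12). Ranged switch
times default to the latest value. The 50/50 triple/dual blend affects
drug cost only (the aspirin component for the triple half); transitions
use the printed blended rates.

Discontinuation is permanent: event-related (25% after OMB, 55.8% after
ICH, resolved in the acute cycle among survivors) and unrelated (4.54%
per cycle on apixaban, 4.80% on VKA, every on-treatment cycle). Off
patients keep off-treatment event rates and accrue no drug or monitoring
cost for the rest of the horizon.

Treatment interruption after an event is cost-only in the source
evidence, so it is implemented as a drug-cost haircut: occupancy in an
acute state pays no drug cost for that cycle (the default one-cycle
interruption coincides with the acute cycle; `interruption_cycles = 0`
disables it). It does not alter transition probabilities.

## Costs, utilities, discounting

Per-cycle drug costs come from the printed per-3-month column (the
per-mg prices of some agents are printed rounded; the per-cycle figures
are internally consistent with a 91.3125-day cycle). The P2Y12 inhibitor
cost is the share-weighted mix per arm. INR monitoring applies to
on-treatment VKA patients only, at EUR 7.05 per test and 4.5 tests per
cycle — the trial frequency is never published, so the frequency is an
exposed configuration value (18 tests/year is within routine Spanish
practice).

Acute events cost their DRG tariff once, at arrival (fatal events
included); post-acute states accrue monthly maintenance costs of every
history event, starting the cycle after the acute cycle (in acute states
the incident event contributes no maintenance yet, prior events do).
Societal runs add indirect acute and monthly costs, published for IS and
ICH only. Utility is the general-population EQ-5D quadratic in age and
sex, multiplied by the acute ratio of the incident event, the post-acute
ratios of remaining history events, and intensity-weighted one-cycle
ratios for short-term events.

Costs and health outcomes are discounted at 3% per year, accrued at cycle
start with **no half-cycle correction** (the convention of the prior
models in this indication; `run$half_cycle_correction` documents the
choice). Life years and time on/off treatment are discounted at the same
rate — the published result table satisfies
`time_on + time_off = total LYs` exactly, which pins that convention.
The horizon is `ceiling((100 - 69.9)/0.25) = 121` cycles.

## Sensitivity analyses

**DSA**: every registered parameter is varied one-way to its 95% CI when
printed, else mean ± 1.96 SE, else ±10%; the tornado ranks absolute INMB
swings. P2Y12 shares (a simplex) are excluded from one-way variation.

**PSA**: gamma distributions (moment-matched) for rates and costs, beta
(moment-matched) for probabilities and utility ratios, lognormal for
hazard ratios with `sigma = (log U - log L)/3.92`, truncated normal
(40–90) for age, and Dirichlet for the P2Y12 shares with concentration =
shares x 2,306 (about half the source trial, i.e. one arm; the published
analysis names only the family). Where no SE is printed (costs, case
fatality), the sampling SE is set so the implied 95% range is ±10%,
matching the DSA convention. Parameters are drawn independently — no
correlation structure is published. Every draw is re-validated; the same
seed reproduces the same draw set bit for bit.

## Synthetic data and the microsimulation oracle

The package ships no third-party data. The life table
(`life_table_es2019_synthetic.csv`) is generated by
`gompertz_life_table()`, a Gompertz hazard calibrated by numerical search
so period life expectancy at birth is 83 years — Spain-like in level,
but smoother than a real national table (no infant-mortality hook, no
accident hump). Results that depend on the old-age mortality shape (life
years, maintenance cost accumulation) therefore reproduce the published
analysis only approximately; the tests' tolerance bands absorb this.

`random_config()` perturbs every PSA-flagged input through its PSA
distribution and re-validates, giving property tests arbitrary-but-valid
configurations. `equal_arm_config()` copies the apixaban arm's rates,
costs and discontinuation onto the VKA arm and zeroes monitoring, making
both arms bitwise-identical pipelines — increments must be exactly zero.

`microsim_oracle()` simulates individuals through the same per-cycle
transition structure the cohort engine uses (with death expanded by
cause so fatal incident events are costed), accruing the same discounted
payoffs. The cohort trace is the expectation of this process, so
agreement within Monte-Carlo error validates propagation and accrual; an
independent brute-force row builder in the test suite validates the rate
math itself against plain scalar code.

## Numerical choices and problem sizes

Transition rows must sum to 1 within 1e-12 and trace rows within 1e-10.
Zero total hazard short-circuits the competing-risk share (stay
probability 1). Beta moment matching falls back to the mean with a
warning when the requested variance is infeasible; degenerate (zero-SE)
parameters return their mean. Life-table lookups clamp below the first
row and above the terminal age.

Tests run the full 121-cycle base case, a 1,000-draw PSA, and
microsimulations of 1,500–4,000 individuals over 12–24 cycles across ~26
random configurations; these sizes give Monte-Carlo standard errors small
enough for 3-sigma checks while keeping the whole suite within a few
minutes on one CPU.

## Known limitations

* Only two concomitant long-term events; no step-up therapy; no
  treatment re-start after discontinuation.
* The synthetic life table approximates Spanish background mortality in
  level, not in shape.
* Joint-state hazard combination is an assumption (product), switchable
  in configuration but not informed by data.
* The INR monitoring frequency and the interruption length are not
  published; both are exposed configuration values.
* PSA draws are independent across parameters.

## A worked base case

```{r base-case, eval = FALSE}
config <- load_parameter_pack()
result <- run_base_case(config)
base_case_table(result)
result$incremental_payer
psa <- run_psa(config, n = 1000, seed = 1)
summary(psa)
plot_ceac(ceac(psa))
```
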
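# oaccea

A lifetime Markov cohort cost-effectiveness model of **apixaban versus
vitamin K antagonists (VKA)** for antithrombotic therapy in patients with
non-valvular atrial fibrillation after an acute coronary syndrome (ACS)
and/or percutaneous coronary intervention (PCI), from the Spanish payer
and societal perspectives.

## The problem and the model

These patients need an oral anticoagulant (OAC) on top of antiplatelet
therapy. Apixaban-based regimens bleed less than VKA-based regimens at
similar ischemic risk, but cost far more per day than acenocoumarol. The
package weighs this trade-off over a lifetime with a state-transition
cohort model (3-month cycles, to age 100):

* **55 health states**: histories of up to two long-term events — MI,
  ischemic stroke (IS), intracranial hemorrhage (ICH), other major bleeds
  (OMB) — each with an acute cycle and a chronic post-acute phase,
  crossed with treatment status (on/off), plus dead. Short-term events
  (CRNMB, urgent revascularization, systemic embolism) accrue one-cycle
  costs and disutilities without changing state.
* **Hazards**: phase-specific trial event rates r (per 100 patient-years)
  scaled by aging HRs (`HR^((age-ref)/10)` after month 6) and
  subsequent-event HRs (product over the history), converted per cycle by
  the competing-risk formula `p_i = (r_i/Σr)(1 − e^{−Σr·t})`. Death
  combines age-banded case fatality, and background mortality from a life
  table adjusted by state-specific excess-mortality HRs, as
  `1 − Π(1 − p_k)`.
* **Strategies**: step-down only — triple-or-dual therapy to OAC
  monotherapy at 6 months (base case), triple → dual → mono, or dual →
  mono; permanent discontinuation (event-related and 4.5–4.8% per cycle
  unrelated) moves patients to off-treatment rates with no drug cost.
* **Outcomes**: discounted (3%/year) costs by component, life years,
  QALYs (multiplicative EQ-5D utility ratios on a general-population
  baseline), events per 100 patients, ICER, and net benefit
  `INMB = WTP·ΔQALY − ΔCost`, `INHB = INMB/WTP` at WTP €20,000/QALY.
* **Uncertainty**: one-way DSA with tornado ranking (CI, else ±1.96 SE,
  else ±10%) and a PSA (gamma rates/costs, beta probabilities/utilities,
  lognormal HRs, Dirichlet P2Y12 shares, truncated-normal age) with
  cost-effectiveness plane and CEAC.

Every published model input ships as a plain-text parameter pack under
`inst/extdata/paper_pack/`. Background mortality uses a **synthetic**
Spain-like Gompertz life table (life expectancy 83 at birth), generated
by `gompertz_life_table()`; an individual-level microsimulation oracle
(`microsim_oracle()`) validates the cohort engine.

## Worked example

```r
library(oaccea)
config <- load_parameter_pack()     # published inputs + synthetic life table
result <- run_base_case(config)
result$incremental_payer
#> <incremental_results> apixaban vs VKA, payer perspective
#>   dCost EUR -653.13 | dLY 0.1336 | dQALY 0.1112
#>   ICER: dominant | INMB EUR 2876.58 | INHB 0.1438 QALY (WTP 20000)
```

Apixaban **dominates** VKA: it saves about €653 per patient (payer
perspective; €3,079 societal) while adding 0.13 life years and 0.11
QALYs, driven by fewer bleeding events (about 12 fewer per 100 patients
lifetime). At €20,000 per QALY this is worth about €2,877 per patient in
net monetary benefit.

```r
psa <- run_psa(config, n = 1000, seed = 1)
summary(psa)$quadrant_share
#>    SE    NE    NW    SW
#> 0.918 0.082 0.000 0.000
plot_ceac(ceac(psa))                 # stays above 0.9 for all WTP <= EUR 50k
dsa <- run_dsa(config)               # tornado: top INMB drivers
run_scenario(config, scenario_spec(vka_agent = "warfarin"))
```

91.8% of PSA draws fall in the South-East quadrant (more QALYs, lower
cost). A command-line front end with the same capabilities lives at
`inst/cli/oaccea.R` (subcommands `run`, `dsa`, `psa`, `ceac`,
`scenario`).

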
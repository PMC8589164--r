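Package: oaccea
Title: Lifetime Markov Cohort Cost-Effectiveness Model of Apixaban
    Versus Vitamin K Antagonists After ACS/PCI in Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lifetime Markov cohort state-transition model comparing
    apixaban-based with vitamin K antagonist (VKA)-based antithrombotic
    strategies in patients with atrial fibrillation after acute coronary
    syndrome or percutaneous coronary intervention, from the Spanish payer
    and societal perspectives. Implements the 3-month-cycle health-state
    engine (up to two concomitant long-term events with acute and
    post-acute phases, treatment step-down and discontinuation), discounted
    cost/QALY accrual, incremental cost-effectiveness measures (ICER, net
    monetary and health benefit), one-way deterministic sensitivity
    analysis with tornado ranking, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, scenario analyses, a synthetic
    life-table generator, and an individual-level microsimulation oracle
    for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
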
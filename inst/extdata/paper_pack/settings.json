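{
  "cohort": {
    "start_age": 69.9,
    "start_age_se": 0.13,
    "male_share": 0.71,
    "male_n": 4614,
    "cohort_n": 6499,
    "initial_postacute_mi_share": 0.612
  },
  "run": {
    "cycle_length_years": 0.25,
    "cycle_days": 91.3125,
    "discount_rate_annual": 0.03,
    "terminal_age": 100,
    "perspective": "payer",
    "wtp": 20000,
    "triple_share_in_blend": 0.5,
    "half_cycle_correction": false,
    "joint_hr_combination": "product"
  },
  "monitoring": {
    "inr_cost_per_test": 7.05,
    "inr_tests_per_cycle": 4.5
  },
  "discontinuation_interruption_cycles": 1,
  "vka_agent": "acenocoumarol",
  "baseline_utility_coeffs": {
    "intercept": 0.9454933,
    "male": 0.0256466,
    "age": -0.0002213,
    "age2": -0.0000294
  },
  "psa": {
    "n_default": 1000,
    "dirichlet_n": 2306,
    "unprinted_rel_ci": 0.10,
    "age_truncation": [40, 90]
  }
}
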
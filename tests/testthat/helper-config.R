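# Shared fixtures: the shipped parameter pack (loaded once) and degenerate
# configurations used by property tests.

test_config <- load_parameter_pack()

# Flat life table: no background mortality below the terminal age.
zero_life_table <- function(terminal_age = 100) {
  suppressWarnings(load_life_table(
    data.frame(age = 0:terminal_age,
               qx = c(rep(0, terminal_age), 1)),
    terminal_age = terminal_age))
}

# All event rates, case fatality, background mortality and discontinuation
# set to zero: the cohort must sit still.
zero_config <- function(config = test_config) {
  config$rates$rate <- 0
  config$fatality$cfr <- 0
  config$discontinuation$prob <- 0
  config$life_table <- zero_life_table()
  validate_model_config(config)
  config
}
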
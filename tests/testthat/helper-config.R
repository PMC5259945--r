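# Shared test fixtures: small configurations built in code.

# default config with a reduced cohort for fast runs
small_cfg <- function(n = 200L, seed = 1L) {
  cfg <- default_config()
  cfg$cohort$n_patients <- as.integer(n)
  cfg$cohort$seed <- as.integer(seed)
  cfg
}

# configuration in which depression can never occur
no_depression_cfg <- function(n = 50L) {
  cfg <- small_cfg(n)
  cfg$natural_history$annual_incidence_minor <- 0
  cfg$natural_history$annual_incidence_major <- 0
  cfg$cohort$baseline_prevalence_major <- 0
  cfg$cohort$baseline_prevalence_minor <- 0
  cfg$cohort$baseline_history_prob <- 0
  cfg
}

# turn off every stochastic disease process (contacts and reviews remain)
inert_cfg <- function(n = 20L) {
  cfg <- no_depression_cfg(n)
  cfg$complications$engine$base_hazard[] <- 0
  cfg
}

# neutralise the bi-directional linkage entirely
unlinked_cfg <- function(n = 150L) {
  cfg <- small_cfg(n)
  cfg$natural_history$hr_complication_on_depression <- 1
  cfg$complications$hr_depression$micro[] <- 1
  cfg$complications$hr_depression$macro[] <- 1
  cfg
}

comp_count_cols <- function(totals) totals[grep("^comp_", names(totals))]
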
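# Shared fixtures for the suite. Everything is built in code; no files.

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# Config with all mortality and asthma switched off: the cohort engine then
# has a closed-form persistence solution used as an exact oracle.
no_mortality_config <- function(cfg = default_config()) {
  cfg$clinical$p_asthma_symptomatic <- 0
  cfg$clinical$p_death_all <- 0
  cfg$clinical$p_death_asthma <- 0
  cfg
}

# Closed-form mid-cycle on-treatment occupancies in the zero-mortality,
# zero-asthma limit: {(1+s1)/2, (s1+s1*s2)/2, s1*s2, s1*s2, ...}.
closed_form_on_effect <- function(d1, d2, horizon = 9) {
  s1 <- 1 - d1
  s2 <- 1 - d2
  c((1 + s1) / 2, (s1 + s1 * s2) / 2, rep(s1 * s2, horizon - 2))
}
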
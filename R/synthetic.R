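# Synthetic-data generators: anchored trial summaries with known true
# effects for validating the indirect-comparison machinery, and randomly
# perturbed parameter sets for fuzzing the cohort engine's invariants.
# Everything is reproducible from (spec, seed); no external data.

#' Specification for a synthetic anchored trial set
#'
#' Emulates the evidence structure behind the indirect comparison: a set of
#' placebo-anchored randomized trials per treatment class (base layout:
#' 4 trials of the first class, 5 of the second, common symptomatic
#' control), with individual patient symptom scores simulated as normal on
#' the RTSS scale -- the working assumption of the SMD framework. Scores
#' are not truncated at zero; that simplification is deliberate.
#'
#' @param true_smd Named numeric: true standardized mean difference versus
#'   control per class (negative = improvement).
#' @param control_mean,control_sd Control-arm score distribution.
#' @param n_per_arm Patients per arm (scalar or named per class).
#' @param n_trials Named integer: trials per class.
#' @param seed RNG seed.
#' @return A `trial_generator_spec`.
#' @export
trial_generator_spec <- function(true_smd = c(five_grass = -0.6, allergoid = -0.4),
                                 control_mean = 4.47, control_sd = 2.0,
                                 n_per_arm = 100,
                                 n_trials = c(five_grass = 4, allergoid = 5),
                                 seed = 42) {
  stopifnot(control_sd > 0, all(n_per_arm >= 10), all(n_trials >= 1))
  out <- list(true_smd = true_smd, control_mean = control_mean,
              control_sd = control_sd, n_per_arm = n_per_arm,
              n_trials = n_trials, seed = seed)
  class(out) <- "trial_generator_spec"
  out
}

#' Generate synthetic anchored trial summaries
#'
#' For each trial, simulates `n_per_arm` individual scores per arm
#' (control: normal(control_mean, control_sd); active: mean shifted by
#' `true_smd * control_sd`) and reports their empirical means, SDs and
#' sizes -- the same summary format the real pipeline consumes via
#' [read_trials_csv()].
#'
#' @param spec A `trial_generator_spec`.
#' @return Data.frame of trial summaries (one row per trial).
#' @export
generate_trials <- function(spec = trial_generator_spec()) {
  set.seed(spec$seed)
  rows <- list()
  for (cl in names(spec$n_trials)) {
    n_arm <- if (length(spec$n_per_arm) > 1) spec$n_per_arm[[cl]] else spec$n_per_arm
    shift <- spec$true_smd[[cl]] * spec$control_sd
    for (i in seq_len(spec$n_trials[[cl]])) {
      active <- rnorm(n_arm, spec$control_mean + shift, spec$control_sd)
      control <- rnorm(n_arm, spec$control_mean, spec$control_sd)
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = sprintf("%s_trial_%02d", cl, i), class = cl,
        mean_active = mean(active), sd_active = sd(active), n_active = n_arm,
        mean_control = mean(control), sd_control = sd(control),
        n_control = n_arm
      )
    }
  }
  do.call(rbind, rows)
}

#' Generate randomly perturbed parameter sets
#'
#' Produces `n` valid configurations with transition probabilities,
#' relative risks, scores, season lengths and unit costs drawn uniformly
#' over wide but admissible ranges, for property-testing the cohort
#' engine (occupancy conservation, monotone absorbing states, sign of the
#' asthma relative-risk effect) across the parameter space.
#'
#' @param config Base `ait_config` to perturb.
#' @param n Number of configurations.
#' @param seed RNG seed.
#' @param rr_range Range for the asthma relative risk (set above 1 to fuzz
#'   the harmful direction).
#' @return List of `n` validated `ait_config`s.
#' @export
generate_parameter_sets <- function(config = default_config(), n = 50,
                                    seed = 7, rr_range = c(0.1, 1)) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    for (arm in c("five_grass", "allergoid")) {
      cfg$arms[[arm]]$disc_y1 <- runif(1, 0, 0.9)
      cfg$arms[[arm]]$disc_y2 <- runif(1, 0, 0.9)
      cfg$arms[[arm]]$rtss <- runif(1, 0, 10)
    }
    cfg$arms$symptomatic$rtss <- runif(1, 2, 12)
    cfg$clinical$p_asthma_symptomatic <- runif(1, 0, 0.2)
    cfg$clinical$rr_asthma_ait <- runif(1, rr_range[1], rr_range[2])
    cfg$clinical$p_death_all <- runif(1, 0, 0.05)
    cfg$clinical$p_death_asthma <- cfg$clinical$p_death_all + runif(1, 0, 0.05)
    cfg$utility$season_months <- runif(1, 0.5, 12)
    cfg$utility$k_rtss_slope <- runif(1, 0, 0.08)
    cfg$costs$c_specialist_visit <- runif(1, 1, 50)
    cfg$costs$c_asthma_annual <- runif(1, 0, 1000)
    out[[i]] <- validate_config(cfg)
  }
  out
}
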
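#' @importFrom stats rnorm rbeta rgamma runif uniroot quantile sd setNames
#' @importFrom utils write.csv modifyList packageVersion
NULL

# Section -> field registry used for validation and for rejecting unknown keys.
.arm_fields <- c(
  "name", "label", "rtss", "disc_y1", "disc_y2",
  "drug_cost_per_month", "drug_cost_annual_fixed",
  "visits_per_treatment_year", "injections_per_treatment_year",
  "supervised_first_dose", "diagnostic_in_year1"
)
.clinical_fields <- c(
  "p_asthma_symptomatic", "rr_asthma_ait", "p_death_all", "p_death_asthma",
  "mean_age_entry"
)
.utility_fields <- c(
  "u_baseline", "k_rtss_slope", "season_months", "asthma_decrement",
  "eq5d_ait", "eq5d_symptomatic"
)
.cost_fields <- c(
  "c_specialist_visit", "c_visit_additional", "c_injection", "c_diagnostics",
  "c_asthma_annual", "c_loratadine_ait", "c_budesonide_ait",
  "c_loratadine_sympt", "c_budesonide_sympt", "visits_per_year_off_treatment",
  "c_labour_hour", "sick_days_symptomatic", "sick_days_ait",
  "productivity_saving_per_season", "remuneration_unit_cost_tables"
)
.settings_fields <- c(
  "horizon_years", "cycle_length", "discount_rate", "wtp_grid", "n_psa",
  "rng_seed", "perspective", "efficacy_se_scale"
)

#' Construct a comparator arm specification
#'
#' An arm bundles one comparator's clinical and cost profile: its pooled
#' on-treatment Rhinoconjunctivitis Total Symptom Score (RTSS, 0--18 points),
#' annual discontinuation probabilities for the first two treatment years
#' (no discontinuation is modelled from year 3 on), and its drug-acquisition
#' and resource-use parameters.
#'
#' Drug cost is modelled two ways: the 5-grass tablet is priced per treated
#' month (pre-seasonal 4 months + co-seasonal months equal to the pollen
#' season length), while the allergoid mix is a fixed annual cost (one pack
#' per year). Either `drug_cost_per_month` or `drug_cost_annual_fixed` is
#' non-zero, never both.
#'
#' @param name Machine name, one of `"five_grass"`, `"allergoid"`,
#'   `"symptomatic"` (free text allowed for user-defined arms).
#' @param label Human-readable label.
#' @param rtss On-treatment symptom score (points).
#' @param disc_y1,disc_y2 Annual discontinuation probabilities, years 1 and 2.
#' @param drug_cost_per_month EUR per month of administration (seasonal dosing).
#' @param drug_cost_annual_fixed EUR per treatment year (fixed annual dosing).
#' @param visits_per_treatment_year Specialist visits per on-treatment year.
#' @param injections_per_treatment_year Injections per on-treatment year.
#' @param supervised_first_dose Whether the first dose is taken under
#'   specialist supervision (billed as one injection fee in cycle 1).
#' @param diagnostic_in_year1 Whether a diagnostic work-up is billed in year 1.
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(name, label = name, rtss,
                     disc_y1 = 0, disc_y2 = 0,
                     drug_cost_per_month = 0, drug_cost_annual_fixed = 0,
                     visits_per_treatment_year = 0,
                     injections_per_treatment_year = 0,
                     supervised_first_dose = FALSE,
                     diagnostic_in_year1 = FALSE) {
  arm <- list(
    name = name, label = label, rtss = rtss,
    disc_y1 = disc_y1, disc_y2 = disc_y2,
    drug_cost_per_month = drug_cost_per_month,
    drug_cost_annual_fixed = drug_cost_annual_fixed,
    visits_per_treatment_year = visits_per_treatment_year,
    injections_per_treatment_year = injections_per_treatment_year,
    supervised_first_dose = supervised_first_dose,
    diagnostic_in_year1 = diagnostic_in_year1
  )
  class(arm) <- "arm_spec"
  validate_arm_spec(arm)
  arm
}

validate_arm_spec <- function(arm) {
  chk <- function(cond, field, msg) {
    if (!cond) stop(sprintf("invalid arm '%s': field '%s' %s",
                            arm$name, field, msg), call. = FALSE)
  }
  chk(is.numeric(arm$rtss) && arm$rtss >= 0, "rtss", "must be >= 0")
  for (f in c("disc_y1", "disc_y2")) {
    chk(is.numeric(arm[[f]]) && arm[[f]] >= 0 && arm[[f]] <= 1, f,
        "must lie in [0, 1]")
  }
  for (f in c("drug_cost_per_month", "drug_cost_annual_fixed",
              "visits_per_treatment_year", "injections_per_treatment_year")) {
    chk(is.numeric(arm[[f]]) && arm[[f]] >= 0, f, "must be >= 0")
  }
  invisible(arm)
}

#' Base-case model configuration
#'
#' Returns the fully parameterized base case: three comparator arms
#' (5-grass tablet, allergoid mix, symptomatic treatment), transition
#' probabilities, utility parameters, unit costs and analysis settings.
#' All printed inputs are encoded at their published values; quantities the
#' published component totals only imply (the RTSS-to-utility slope, per-arm
#' visit and injection counts, the baseline utility and the per-season
#' productivity saving) carry the values recovered by the package's
#' calibration routines (see [calibrate_all()]), which reproduce those
#' totals when fed back through the model.
#'
#' Key base-case values: discontinuation 0.29/0.28 (5-grass) and 0.41/0.34
#' (allergoid); asthma incidence 0.0046/yr under symptomatic care, relative
#' risk 0.505 under immunotherapy; mortality 0.00046 (0.00069 with asthma);
#' RTSS 3.26 / 3.64 / 4.47; 3-year drug acquisition EUR 2,100.10 (5-grass,
#' 21 treated months) and EUR 1,449.60 (allergoid); 9-year horizon, 3%
#' annual discount on costs and effects, 3-month pollen season.
#'
#' @return An object of class `ait_config` with sections `arms`, `clinical`,
#'   `utility`, `costs`, `settings`.
#' @export
default_config <- function() {
  cfg <- list(
    arms = list(
      five_grass = arm_spec(
        name = "five_grass", label = "5-grass tablet",
        rtss = 3.26, disc_y1 = 0.29, disc_y2 = 0.28,
        drug_cost_per_month = 2100.10 / 21,    # 3-year pack over 21 treated months
        visits_per_treatment_year = 3.43154406,    # calibrated, see calibrate_resource_counts()
        injections_per_treatment_year = 0,
        supervised_first_dose = TRUE,
        diagnostic_in_year1 = TRUE
      ),
      allergoid = arm_spec(
        name = "allergoid", label = "Allergoid mix",
        rtss = 3.64, disc_y1 = 0.41, disc_y2 = 0.34,
        drug_cost_annual_fixed = 1449.60 / 3,  # one pack per treatment year
        visits_per_treatment_year = 5.14744688,    # calibrated
        injections_per_treatment_year = 8.07011983, # calibrated
        supervised_first_dose = FALSE,
        diagnostic_in_year1 = TRUE
      ),
      symptomatic = arm_spec(
        name = "symptomatic", label = "Symptomatic treatment",
        rtss = 4.47
      )
    ),
    clinical = list(
      p_asthma_symptomatic = 0.0046,
      rr_asthma_ait = 0.505,
      p_death_all = 0.00046,
      p_death_asthma = 0.00069,
      mean_age_entry = 29
    ),
    utility = list(
      u_baseline = 0.96997356,       # calibrated, see calibrate_baseline_utility()
      k_rtss_slope = 0.05908002,    # calibrated, see calibrate_utility_slope()
      season_months = 3,
      asthma_decrement = 0,
      eq5d_ait = 0.976,
      eq5d_symptomatic = 0.947
    ),
    costs = list(
      c_specialist_visit = 13.29,
      c_visit_additional = 3.69,
      c_injection = 5.11,
      c_diagnostics = 20.61,
      c_asthma_annual = 186.30,
      c_loratadine_ait = 5.14,
      c_budesonide_ait = 2.19,
      c_loratadine_sympt = 7.54,
      c_budesonide_sympt = 3.83,
      visits_per_year_off_treatment = 1.9,
      c_labour_hour = 30.70,
      sick_days_symptomatic = 3.7,
      sick_days_ait = 1.2,
      productivity_saving_per_season = 133.28842 # calibrated
      # remuneration_unit_cost_tables: optional, scenarios 1-2 only
    ),
    settings = list(
      horizon_years = 9L,
      cycle_length = 1,
      discount_rate = 0.03,
      wtp_grid = seq(0, 50000, by = 1000),
      n_psa = 1000L,
      rng_seed = 1L,
      perspective = "payer",
      efficacy_se_scale = 0.15336  # calibrated, see calibrate_efficacy_se()
    )
  )
  class(cfg) <- "ait_config"
  validate_config(cfg)
}

#' Validate a model configuration
#'
#' Checks every structural invariant: probabilities in \[0,1\], non-negative
#' costs and scores, asthma mortality at least all-cause mortality, season
#' length within a year, a horizon covering the 3-year treatment period,
#' and the symptomatic arm carrying no treatment costs, discontinuation or
#' injections.
#'
#' @param config An `ait_config` (or plain list with the same sections).
#' @return The validated config, invisibly classed `ait_config`.
#' @export
validate_config <- function(config) {
  fail <- function(field, msg) {
    stop(sprintf("config validation error: '%s' %s", field, msg), call. = FALSE)
  }
  need <- function(section, fields) {
    miss <- setdiff(fields, names(config[[section]]))
    if (length(miss)) fail(paste0(section, "$", miss[1]), "is missing")
  }
  need("clinical", .clinical_fields)
  need("utility", setdiff(.utility_fields, "asthma_decrement"))
  need("costs", setdiff(.cost_fields, "remuneration_unit_cost_tables"))
  need("settings", setdiff(.settings_fields, "efficacy_se_scale"))

  for (arm in config$arms) validate_arm_spec(arm)

  cl <- config$clinical
  for (f in c("p_asthma_symptomatic", "p_death_all", "p_death_asthma")) {
    if (cl[[f]] < 0 || cl[[f]] > 1) fail(paste0("clinical$", f), "must lie in [0, 1]")
  }
  if (cl$rr_asthma_ait < 0) fail("clinical$rr_asthma_ait", "must be >= 0")
  if (cl$p_death_asthma < cl$p_death_all) {
    fail("clinical$p_death_asthma", "must be >= p_death_all")
  }

  u <- config$utility
  if (u$u_baseline < 0 || u$u_baseline > 1) fail("utility$u_baseline", "must lie in [0, 1]")
  if (u$k_rtss_slope < 0) fail("utility$k_rtss_slope", "must be >= 0")
  if (u$season_months < 0 || u$season_months > 12) {
    fail("utility$season_months", "must lie in [0, 12]")
  }

  co <- config$costs
  for (f in setdiff(.cost_fields, "remuneration_unit_cost_tables")) {
    if (!is.numeric(co[[f]]) || co[[f]] < 0) fail(paste0("costs$", f), "must be >= 0")
  }

  st <- config$settings
  if (st$discount_rate < 0) fail("settings$discount_rate", "must be >= 0")
  if (st$horizon_years < 3) fail("settings$horizon_years", "must cover the 3-year treatment period")
  if (!st$perspective %in% c("payer", "societal")) {
    fail("settings$perspective", "must be 'payer' or 'societal'")
  }
  if (st$n_psa < 1) fail("settings$n_psa", "must be >= 1")

  sym <- config$arms$symptomatic
  if (!is.null(sym)) {
    if (sym$disc_y1 != 0 || sym$disc_y2 != 0) {
      fail("arms$symptomatic$disc_y1", "must be 0 (no treatment to discontinue)")
    }
    if (sym$drug_cost_per_month != 0 || sym$drug_cost_annual_fixed != 0 ||
        sym$injections_per_treatment_year != 0) {
      fail("arms$symptomatic", "must carry zero treatment costs and injections")
    }
  }
  class(config) <- "ait_config"
  invisible(config)
}

#' @export
print.ait_config <- function(x, ...) {
  cat("<ait_config>\n")
  cat(sprintf("  arms: %s\n", paste(vapply(x$arms, `[[`, "", "label"),
                                    collapse = ", ")))
  cat(sprintf("  horizon: %d years, discount %.1f%%, season %.3g months, perspective %s\n",
              x$settings$horizon_years, 100 * x$settings$discount_rate,
              x$utility$season_months, x$settings$perspective))
  cat(sprintf("  utility slope: %.4f / RTSS point; baseline utility %.4f\n",
              x$utility$k_rtss_slope, x$utility$u_baseline))
  invisible(x)
}

#' Read a model configuration from JSON
#'
#' Reads a JSON configuration with sections `arms`, `clinical`, `utility`,
#' `costs`, `settings`. Absent fields take the base-case defaults from
#' [default_config()]; unknown sections or keys are rejected (fail fast)
#' so typos cannot silently fall back to defaults. The bundled base case
#' lives at `system.file("extdata", "base_case.json", package = "aitcea")`
#' and the field registry at `config_schema.json` alongside it.
#'
#' @param path Path to a JSON config file.
#' @return A validated `ait_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("config error: cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  unknown <- setdiff(names(raw), c("arms", "clinical", "utility", "costs", "settings"))
  if (length(unknown)) {
    stop("config validation error: unknown section(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- unclass(default_config())

  reject_unknown <- function(got, allowed, where) {
    bad <- setdiff(names(got), allowed)
    if (length(bad)) {
      stop(sprintf("config validation error: unknown key(s) in %s: %s",
                   where, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(raw$arms)) {
    for (arm_name in names(raw$arms)) {
      reject_unknown(raw$arms[[arm_name]], .arm_fields, paste0("arms$", arm_name))
      base <- cfg$arms[[arm_name]]
      if (is.null(base)) {
        base <- list(name = arm_name, label = arm_name, rtss = 0, disc_y1 = 0,
                     disc_y2 = 0, drug_cost_per_month = 0,
                     drug_cost_annual_fixed = 0, visits_per_treatment_year = 0,
                     injections_per_treatment_year = 0,
                     supervised_first_dose = FALSE, diagnostic_in_year1 = FALSE)
      }
      merged <- modifyList(unclass(base), raw$arms[[arm_name]])
      class(merged) <- "arm_spec"
      cfg$arms[[arm_name]] <- merged
    }
  }
  for (section in c("clinical", "utility", "costs", "settings")) {
    if (is.null(raw[[section]])) next
    allowed <- switch(section, clinical = .clinical_fields,
                      utility = .utility_fields, costs = .cost_fields,
                      settings = .settings_fields)
    reject_unknown(raw[[section]], allowed, section)
    cfg[[section]] <- modifyList(cfg[[section]], raw[[section]])
  }
  class(cfg) <- "ait_config"
  validate_config(cfg)
}

#' Write a model configuration to JSON
#'
#' Serializes losslessly: `load_config(write_config(cfg, path))` returns a
#' configuration identical to `cfg`.
#'
#' @param config An `ait_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  out <- unclass(config)
  out$arms <- lapply(out$arms, unclass)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Annual drug-acquisition cost of an arm
#'
#' For seasonally dosed products (per-month pricing, e.g. the 5-grass
#' tablet) the annual cost is `drug_cost_per_month * (4 + season_months)`:
#' four pre-seasonal months plus co-seasonal use for the length of the
#' pollen season. Fixed-pack products (the allergoid mix) cost
#' `drug_cost_annual_fixed` per treatment year regardless of season length;
#' the symptomatic arm costs nothing.
#'
#' @param arm An `arm_spec`.
#' @param season_months Pollen season length in months, in (0, 12].
#' @return EUR per on-treatment year.
#' @examples
#' cfg <- default_config()
#' annual_drug_cost(cfg$arms$five_grass, 3)   # ~700.03
#' annual_drug_cost(cfg$arms$allergoid, 3)    # 483.20
#' @export
annual_drug_cost <- function(arm, season_months) {
  if (!is.numeric(season_months) || season_months <= 0 || season_months > 12) {
    stop("config validation error: 'season_months' must lie in (0, 12]",
         call. = FALSE)
  }
  arm$drug_cost_per_month * (4 + season_months) + arm$drug_cost_annual_fixed
}
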
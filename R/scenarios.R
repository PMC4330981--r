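# The five scenario analyses, expressed as pure transformations of the base
# configuration. Scenarios 1-2 swap remuneration unit-cost tables that are
# not published (per-setting lump-sum / ambulatory / fee-schedule prices);
# they run only when the user supplies such a table and placeholder tables
# shipped with the package are explicitly marked non-validated. Scenario 3
# switches to the societal perspective (adds the calibrated productivity
# stream), scenario 4 replaces the seasonal symptom-utility map with
# year-round EQ-5D utilities (0.976 while the treatment effect persists,
# 0.947 otherwise), and scenario 5 shortens the pollen season to two months
# (which also shortens co-seasonal 5-grass administration by one month).

#' Scenario specification
#'
#' @param id Scenario number 1--5 (or free integer for user scenarios).
#' @param label Human-readable label.
#' @param overrides Named list of config overrides (nested paths as nested
#'   lists), applied by [apply_scenario()] without touching the base.
#' @param eq5d_mode Use the year-round EQ-5D utility pair for QALYs.
#' @param unit_cost_table Optional named list of per-setting unit-cost
#'   overrides (`c_specialist_visit`, `c_injection`, `c_diagnostics`, ...)
#'   for remuneration scenarios.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(id, label, overrides = list(), eq5d_mode = FALSE,
                          unit_cost_table = NULL) {
  out <- list(id = id, label = label, overrides = overrides,
              eq5d_mode = eq5d_mode, unit_cost_table = unit_cost_table)
  class(out) <- "scenario_spec"
  out
}

#' The five published scenario analyses
#'
#' @param unit_cost_tables Optional named list with entries `lump_sum` and
#'   `ambulatory`, each a named list of unit-cost overrides, enabling
#'   scenarios 1--2. Without them those scenarios error when applied.
#' @return Named list of `scenario_spec`s.
#' @export
standard_scenarios <- function(unit_cost_tables = NULL) {
  list(
    s1 = scenario_spec(1, "100% lump sums",
                       unit_cost_table = unit_cost_tables$lump_sum),
    s2 = scenario_spec(2, "100% ambulatory setting",
                       unit_cost_table = unit_cost_tables$ambulatory),
    s3 = scenario_spec(3, "Societal perspective",
                       overrides = list(settings = list(perspective = "societal"))),
    s4 = scenario_spec(4, "Changing utilities (year-round EQ-5D)",
                       eq5d_mode = TRUE),
    s5 = scenario_spec(5, "Shorter pollen season (2 months)",
                       overrides = list(utility = list(season_months = 2)))
  )
}

#' Apply a scenario to a base configuration
#'
#' Pure transformation: returns a new validated config, leaving `base`
#' untouched. Remuneration scenarios (a `unit_cost_table` present in the
#' spec) replace the listed unit costs; an id of 1 or 2 without a table is
#' an error, since the per-setting catalogue prices are not part of the
#' shipped inputs.
#'
#' @param base The base `ait_config`.
#' @param spec A `scenario_spec`.
#' @return A validated `ait_config` (with attribute `eq5d_mode`).
#' @export
apply_scenario <- function(base, spec) {
  cfg <- unclass(base)
  if (spec$id %in% c(1, 2) && is.null(spec$unit_cost_table)) {
    stop("scenario ", spec$id, " ('", spec$label, "') needs a per-setting ",
         "unit-cost table; the remuneration catalogue prices are not part ",
         "of the shipped base case", call. = FALSE)
  }
  if (!is.null(spec$unit_cost_table)) {
    unknown <- setdiff(names(spec$unit_cost_table), .cost_fields)
    if (length(unknown)) {
      stop("unknown unit-cost field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg$costs <- modifyList(cfg$costs, spec$unit_cost_table)
  }
  for (section in names(spec$overrides)) {
    cfg[[section]] <- modifyList(cfg[[section]], spec$overrides[[section]])
  }
  class(cfg) <- "ait_config"
  cfg <- validate_config(cfg)
  attr(cfg, "eq5d_mode") <- isTRUE(spec$eq5d_mode)
  cfg
}

#' Run all scenario analyses
#'
#' Runs the base case plus every applicable scenario and reports, per
#' scenario and contrast (5-grass vs allergoid mix, 5-grass vs symptomatic
#' treatment), the discounted incremental QALYs, incremental cost and
#' ICER. Scenarios 1--2 are skipped with a message unless unit-cost tables
#' are supplied.
#'
#' @param base Calibrated base `ait_config`.
#' @param scenarios List of `scenario_spec`s (defaults to
#'   [standard_scenarios()]).
#' @return Data.frame with columns `scenario`, `label`, `comparator`,
#'   `delta_qaly`, `delta_cost`, `icer`.
#' @export
run_all_scenarios <- function(base, scenarios = standard_scenarios()) {
  collect <- function(cfg, eq5d_mode, id, label) {
    res <- run_base_case(cfg, eq5d_mode = eq5d_mode)
    inc <- res$incrementals[res$incrementals$discounted, ]
    data.frame(scenario = id, label = label, comparator = inc$comparator,
               delta_qaly = inc$delta_qaly, delta_cost = inc$delta_cost,
               icer = inc$delta_cost / inc$delta_qaly)
  }
  rows <- list(collect(base, FALSE, 0, "Base case"))
  for (sc in scenarios) {
    if (sc$id %in% c(1, 2) && is.null(sc$unit_cost_table)) {
      message("scenario ", sc$id, " skipped: no per-setting unit-cost table supplied")
      next
    }
    cfg <- apply_scenario(base, sc)
    rows[[length(rows) + 1]] <- collect(cfg, isTRUE(attr(cfg, "eq5d_mode")),
                                        sc$id, sc$label)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Placeholder per-setting unit-cost tables (synthetic, non-validated)
#'
#' The published analysis priced the remuneration scenarios from the
#' German fee catalogues, whose per-setting prices are not reproduced in
#' the shipped inputs. These tables are synthetic placeholders that
#' scale the weighted-average unit costs (lump sums cheaper per contact,
#' ambulatory costlier) purely so the scenario machinery can be exercised;
#' results under them are NOT validated against any published figure.
#'
#' @return Named list with `lump_sum` and `ambulatory` unit-cost tables.
#' @export
placeholder_unit_cost_tables <- function() {
  list(
    lump_sum = list(c_specialist_visit = 10.50, c_injection = 3.80,
                    c_diagnostics = 16.00),
    ambulatory = list(c_specialist_visit = 18.00, c_injection = 7.50,
                      c_diagnostics = 28.00)
  )
}
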
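#' Annual discount factor
#'
#' Discounting follows the convention `(1 + rate)^-(cycle - 1)`: the first
#' model year is valued undiscounted and every later year is discounted
#' back to model entry.
#'
#' @param cycle Cycle index (vectorized), 1-based.
#' @param rate Annual discount rate, >= 0.
#' @return Discount factor(s) in (0, 1].
#' @export
discount_factor <- function(cycle, rate) {
  if (any(cycle < 1)) stop("cycle must be >= 1", call. = FALSE)
  if (rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  (1 + rate)^-(cycle - 1)
}

# Symptom score experienced in a regime: the arm's on-treatment RTSS while
# the effect persists, the symptomatic-treatment RTSS otherwise.
.regime_rtss <- function(regime, arm, symptomatic_rtss) {
  if (regime %in% c("active", "on_treatment", "completed_treatment")) {
    arm$rtss
  } else {
    symptomatic_rtss
  }
}

#' Annual utility of a health state
#'
#' The seasonal symptom burden enters linearly: utility for one alive year
#' is `u_baseline - (season_months / 12) * k_rtss_slope * rtss -
#' asthma_decrement * [asthma]`, where `rtss` is the arm's on-treatment
#' score while the immunotherapy effect persists and the symptomatic score
#' after discontinuation (or in the symptomatic arm). The slope
#' `k_rtss_slope` is the per-RTSS-point utility decrement of the
#' preference-based rhinitis symptom utility index proxy, applied only
#' during the pollen season. Dead contributes 0. Negative utilities are
#' clamped to 0 with a warning.
#'
#' @param state State name: one of `"active"`, `"on_treatment"`,
#'   `"completed_treatment"`, `"discontinued"`, `"symptomatic"`,
#'   `"symptomatic_only"`, `"dead"`.
#' @param arm The `arm_spec` whose score applies while on effect.
#' @param utility The `utility` section of an `ait_config`.
#' @param asthma Whether the chronic-asthma decrement applies.
#' @param symptomatic_rtss Off-effect symptom score (base case 4.47).
#' @return Utility for one year in the state.
#' @export
cycle_utility <- function(state, arm, utility, asthma = FALSE,
                          symptomatic_rtss = 4.47) {
  if (state == "dead") return(0)
  rtss <- .regime_rtss(state, arm, symptomatic_rtss)
  u <- utility$u_baseline -
    (utility$season_months / 12) * utility$k_rtss_slope * rtss -
    (if (asthma) utility$asthma_decrement %||% 0 else 0)
  if (u < 0) {
    warning("utility below 0 clamped to 0", call. = FALSE)
    u <- 0
  }
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accumulate component costs over a cohort trace
#'
#' Values each cost component per cycle against the half-cycle-corrected
#' mid-cycle occupancies and unit costs:
#' \describe{
#'   \item{treatment}{on-treatment share (active regime, cycles 1--3) times
#'     the arm's annual drug cost.}
#'   \item{visits}{on-treatment share times the arm's visits per treatment
#'     year, plus every other alive patient (discontinued, symptomatic, and
#'     treatment completers from cycle 4) at the off-treatment rate of 1.9
#'     visits/year, at the specialist-visit fee.}
#'   \item{injection_control}{on-treatment share times injections per
#'     treatment year at the injection fee; a supervised first dose adds one
#'     injection fee against the cycle-1 on-treatment share.}
#'   \item{diagnostics}{one diagnostic work-up, booked cycle 1 for the full
#'     cohort, immunotherapy arms only.}
#'   \item{other_drugs}{seasonal symptomatic medication: on-effect share at
#'     the (lower) AIT-arm loratadine+budesonide season cost, off-effect
#'     share at the symptomatic-arm season cost.}
#'   \item{asthma}{alive asthmatic share times the annual asthma cost.}
#'   \item{productivity}{societal perspective only: off-effect alive share
#'     times the per-season productivity saving forgone relative to
#'     patients with a persisting treatment effect.}
#' }
#'
#' @param trace A `cohort_trace`.
#' @param arm The matching `arm_spec`.
#' @param costs The `costs` section of an `ait_config`.
#' @param settings The `settings` section (horizon, discount rate,
#'   perspective).
#' @param season_months Pollen season length (months).
#' @return A `cost_breakdown`: data.frame with one row per component plus a
#'   total row, columns `component`, `undiscounted`, `discounted`.
#' @export
accumulate_costs <- function(trace, arm, costs, settings, season_months = 3) {
  H <- trace$horizon
  d <- discount_factor(seq_len(H), settings$discount_rate)

  on_trt <- trace_on_treatment(trace)
  on_eff <- trace_on_effect(trace)
  off_eff <- trace_off_effect(trace)
  alive <- on_eff + off_eff
  off_visits <- alive - on_trt   # completers join the off-treatment schedule

  per <- list()
  per$treatment <- on_trt * annual_drug_cost(arm, season_months)
  per$visits <- (on_trt * arm$visits_per_treatment_year +
                   off_visits * costs$visits_per_year_off_treatment) *
    costs$c_specialist_visit
  inj <- on_trt * arm$injections_per_treatment_year * costs$c_injection
  if (isTRUE(arm$supervised_first_dose)) {
    inj[1] <- inj[1] + on_trt[1] * costs$c_injection
  }
  per$injection_control <- inj
  diag <- numeric(H)
  if (isTRUE(arm$diagnostic_in_year1)) diag[1] <- costs$c_diagnostics
  per$diagnostics <- diag
  per$other_drugs <- on_eff * (costs$c_loratadine_ait + costs$c_budesonide_ait) +
    off_eff * (costs$c_loratadine_sympt + costs$c_budesonide_sympt)
  per$asthma <- trace_asthma(trace) * costs$c_asthma_annual
  per$productivity <- if (identical(settings$perspective, "societal")) {
    off_eff * costs$productivity_saving_per_season
  } else {
    numeric(H)
  }

  comp <- names(per)
  out <- data.frame(
    component = comp,
    undiscounted = vapply(per, sum, 0),
    discounted = vapply(per, function(x) sum(x * d), 0),
    row.names = NULL
  )
  out <- rbind(out, data.frame(component = "total",
                               undiscounted = sum(out$undiscounted),
                               discounted = sum(out$discounted)))
  class(out) <- c("cost_breakdown", "data.frame")
  out
}

#' Accumulate QALYs over a cohort trace
#'
#' Sums, over cycles and states, mid-cycle occupancy times the state's
#' annual utility (see [cycle_utility()]), discounted and undiscounted.
#' When `eq5d_mode = TRUE` the seasonal symptom-utility map is replaced by
#' year-round annual utilities: `eq5d_ait` while the treatment effect
#' persists and `eq5d_symptomatic` otherwise (the changed-utilities
#' scenario), independent of the calibrated slope.
#'
#' @param trace A `cohort_trace`.
#' @param arm The matching `arm_spec`.
#' @param utility The `utility` section of an `ait_config`.
#' @param settings The `settings` section.
#' @param symptomatic_rtss Off-effect symptom score.
#' @param eq5d_mode Use the year-round EQ-5D utility pair instead of the
#'   seasonal symptom-score map.
#' @return Named list `qalys_discounted`, `qalys_undiscounted`.
#' @export
accumulate_qalys <- function(trace, arm, utility, settings,
                             symptomatic_rtss = 4.47, eq5d_mode = FALSE) {
  H <- trace$horizon
  d <- discount_factor(seq_len(H), settings$discount_rate)
  if (eq5d_mode) {
    u_on <- utility$eq5d_ait
    u_off <- utility$eq5d_symptomatic
    per_noasthma <- trace$mid[, "active"] * u_on +
      (trace$mid[, "discontinued"] + trace$mid[, "symptomatic"]) * u_off
    a_dec <- utility$asthma_decrement %||% 0
    per_asthma <- trace$mid[, "active_asthma"] * (u_on - a_dec) +
      (trace$mid[, "discontinued_asthma"] + trace$mid[, "symptomatic_asthma"]) *
      (u_off - a_dec)
    per <- per_noasthma + per_asthma
  } else {
    u_on <- cycle_utility("active", arm, utility, FALSE, symptomatic_rtss)
    u_on_a <- cycle_utility("active", arm, utility, TRUE, symptomatic_rtss)
    u_off <- cycle_utility("symptomatic", arm, utility, FALSE, symptomatic_rtss)
    u_off_a <- cycle_utility("symptomatic", arm, utility, TRUE, symptomatic_rtss)
    per <- trace$mid[, "active"] * u_on +
      trace$mid[, "active_asthma"] * u_on_a +
      (trace$mid[, "discontinued"] + trace$mid[, "symptomatic"]) * u_off +
      (trace$mid[, "discontinued_asthma"] + trace$mid[, "symptomatic_asthma"]) * u_off_a
  }
  list(qalys_discounted = sum(per * d), qalys_undiscounted = sum(per))
}

#' Run one arm end to end
#'
#' Propagates the cohort and accumulates costs and QALYs for a single arm
#' under a configuration.
#'
#' @param config An `ait_config`.
#' @param arm_name Name of the arm in `config$arms`.
#' @param eq5d_mode Passed to [accumulate_qalys()].
#' @return An `arm_result`: list with `arm`, `trace`, `costs`
#'   (a `cost_breakdown`), `qalys_discounted`, `qalys_undiscounted`,
#'   `cost_discounted`, `cost_undiscounted`.
#' @export
run_arm <- function(config, arm_name, eq5d_mode = FALSE) {
  arm <- config$arms[[arm_name]]
  if (is.null(arm)) stop("unknown arm: ", arm_name, call. = FALSE)
  sym_rtss <- config$arms$symptomatic$rtss %||% 4.47
  trace <- run_cohort(arm, config$clinical, config$settings)
  costs <- accumulate_costs(trace, arm, config$costs, config$settings,
                            config$utility$season_months)
  q <- accumulate_qalys(trace, arm, config$utility, config$settings,
                        symptomatic_rtss = sym_rtss, eq5d_mode = eq5d_mode)
  res <- list(
    arm = arm_name, trace = trace, costs = costs,
    qalys_discounted = q$qalys_discounted,
    qalys_undiscounted = q$qalys_undiscounted,
    cost_discounted = costs$discounted[costs$component == "total"],
    cost_undiscounted = costs$undiscounted[costs$component == "total"]
  )
  class(res) <- "arm_result"
  res
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s\n", x$arm))
  cat(sprintf("  QALYs: %.3f discounted / %.3f undiscounted\n",
              x$qalys_discounted, x$qalys_undiscounted))
  cat(sprintf("  costs: EUR %.0f discounted / EUR %.0f undiscounted\n",
              x$cost_discounted, x$cost_undiscounted))
  invisible(x)
}

#' Pairwise incremental comparison
#'
#' Computes incremental cost, incremental QALYs, the incremental
#' cost-effectiveness ratio and net monetary benefit of `reference` over
#' `comparator` (deltas are reference minus comparator). Dominance is
#' labelled: `"dominant"` when the reference is cheaper and more effective,
#' `"dominated"` when costlier and less effective, `"undefined"` when the
#' QALY difference is zero.
#'
#' @param reference,comparator `arm_result` objects from identical settings.
#' @param wtp Willingness-to-pay threshold (EUR/QALY) for the net monetary
#'   benefit `wtp * delta_qaly - delta_cost`.
#' @param discounted Compare discounted (default) or undiscounted totals.
#' @return An `incremental_result`: list with `delta_cost`, `delta_qaly`,
#'   `icer` (number or dominance label), `nmb`, `wtp`, arm names.
#' @examples
#' cfg <- default_config()
#' compare_arms(run_arm(cfg, "five_grass"), run_arm(cfg, "allergoid"))
#' @export
compare_arms <- function(reference, comparator, wtp = 20000,
                         discounted = TRUE) {
  dc <- if (discounted) {
    reference$cost_discounted - comparator$cost_discounted
  } else {
    reference$cost_undiscounted - comparator$cost_undiscounted
  }
  de <- if (discounted) {
    reference$qalys_discounted - comparator$qalys_discounted
  } else {
    reference$qalys_undiscounted - comparator$qalys_undiscounted
  }
  icer <- if (de > 0 && dc > 0) {
    dc / de
  } else if (de > 0 && dc <= 0) {
    "dominant"
  } else if (de < 0 && dc > 0) {
    "dominated"
  } else if (de == 0) {
    "undefined"
  } else {
    dc / de   # less effective and cheaper: south-west ICER
  }
  out <- list(reference = reference$arm, comparator = comparator$arm,
              delta_cost = dc, delta_qaly = de, icer = icer,
              nmb = wtp * de - dc, wtp = wtp, discounted = discounted)
  class(out) <- "incremental_result"
  out
}

#' @export
print.incremental_result <- function(x, ...) {
  icer <- if (is.numeric(x$icer)) sprintf("EUR %.0f/QALY", x$icer) else x$icer
  cat(sprintf("<incremental_result> %s vs %s (%s)\n", x$reference,
              x$comparator, if (x$discounted) "discounted" else "undiscounted"))
  cat(sprintf("  dCost EUR %.1f, dQALY %.4f, ICER %s, NMB(%.0f) EUR %.1f\n",
              x$delta_cost, x$delta_qaly, icer, x$wtp, x$nmb))
  invisible(x)
}

#' Run the full base case
#'
#' Runs every arm in the configuration and the two headline contrasts
#' (5-grass tablet vs allergoid mix, 5-grass tablet vs symptomatic
#' treatment), discounted and undiscounted.
#'
#' @param config An `ait_config`.
#' @param eq5d_mode Passed through to [run_arm()].
#' @return A `base_case_result`: list with `arms` (named `arm_result`s) and
#'   `incrementals` (data.frame with one row per contrast and discounting).
#' @export
run_base_case <- function(config, eq5d_mode = FALSE) {
  arms <- lapply(names(config$arms), run_arm, config = config,
                 eq5d_mode = eq5d_mode)
  names(arms) <- names(config$arms)
  contrasts <- list(c("five_grass", "allergoid"), c("five_grass", "symptomatic"))
  contrasts <- Filter(function(p) all(p %in% names(arms)), contrasts)
  rows <- list()
  for (p in contrasts) {
    for (disc in c(TRUE, FALSE)) {
      cmp <- compare_arms(arms[[p[1]]], arms[[p[2]]], discounted = disc)
      rows[[length(rows) + 1]] <- data.frame(
        reference = p[1], comparator = p[2],
        discounted = disc, delta_cost = cmp$delta_cost,
        delta_qaly = cmp$delta_qaly,
        icer = if (is.numeric(cmp$icer)) cmp$icer else NA_real_,
        icer_label = if (is.numeric(cmp$icer)) "" else cmp$icer
      )
    }
  }
  out <- list(arms = arms, incrementals = do.call(rbind, rows))
  class(out) <- "base_case_result"
  out
}

#' @export
print.base_case_result <- function(x, ...) {
  cat("<base_case_result>\n")
  for (a in x$arms) {
    cat(sprintf("  %-12s QALY %.3f (disc) cost EUR %7.0f (disc)\n",
                a$arm, a$qalys_discounted, a$cost_discounted))
  }
  inc <- x$incrementals[x$incrementals$discounted, ]
  for (i in seq_len(nrow(inc))) {
    cat(sprintf("  %s vs %s: dC EUR %.0f, dQ %.3f, ICER %s\n",
                inc$reference[i], inc$comparator[i], inc$delta_cost[i],
                inc$delta_qaly[i],
                ifelse(is.na(inc$icer[i]), inc$icer_label[i],
                       sprintf("EUR %.0f/QALY", inc$icer[i]))))
  }
  invisible(x)
}
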
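# Internal state space: the "active" regime (on immunotherapy in cycles 1-3,
# treatment completed thereafter) crossed with an absorbing asthma flag, plus
# discontinued and symptomatic-only regimes and a single absorbing dead state.
# The on_treatment / completed_treatment distinction of the reported trace is
# purely a function of the cycle index, so the engine carries 7 states.
.states <- c("active", "active_asthma",
             "discontinued", "discontinued_asthma",
             "symptomatic", "symptomatic_asthma",
             "dead")

#' Annual transition matrix for one cycle
#'
#' Builds the state-to-state transition probabilities for a given arm and
#' cycle. Within a cycle, competing events are composed multiplicatively in
#' the order death, then treatment discontinuation, then asthma onset; at
#' the modelled magnitudes the ordering changes results by well under 0.1%.
#' Discontinuation applies in cycles 1 and 2 only (`disc_y1`, `disc_y2`);
#' year-3 survivors complete treatment and remain in the active regime.
#' Asthma incidence is `p_asthma_symptomatic * rr_asthma_ait` while the
#' immunotherapy effect persists (active regime) and
#' `p_asthma_symptomatic` otherwise -- including the cycle in which a
#' patient discontinues, who reverts immediately to the symptomatic risk.
#' Asthma is absorbing; death probability is `p_death_all` without and
#' `p_death_asthma` with asthma (the latter read as the total annual death
#' probability in the asthma state).
#'
#' @param arm An `arm_spec`.
#' @param clinical The `clinical` section of an `ait_config`.
#' @param cycle Cycle index, 1-based.
#' @return A 7x7 row-stochastic matrix over the engine's state space.
#' @export
transition_matrix <- function(arm, clinical, cycle) {
  if (cycle < 1) stop("cycle must be >= 1", call. = FALSE)
  d <- if (cycle == 1) arm$disc_y1 else if (cycle == 2) arm$disc_y2 else 0
  pd0 <- clinical$p_death_all
  pd1 <- clinical$p_death_asthma
  pa_sym <- clinical$p_asthma_symptomatic
  pa_ait <- pa_sym * clinical$rr_asthma_ait
  for (p in c(d, pd0, pd1, pa_sym, pa_ait)) {
    if (p < 0 || p > 1) {
      stop("parameterization error: composed transition probability outside [0, 1]",
           call. = FALSE)
    }
  }
  P <- matrix(0, 7, 7, dimnames = list(.states, .states))
  # active, no asthma: death -> discontinue -> asthma (at destination regime's risk)
  P["active", "dead"] <- pd0
  P["active", "discontinued_asthma"] <- (1 - pd0) * d * pa_sym
  P["active", "discontinued"] <- (1 - pd0) * d * (1 - pa_sym)
  P["active", "active_asthma"] <- (1 - pd0) * (1 - d) * pa_ait
  P["active", "active"] <- (1 - pd0) * (1 - d) * (1 - pa_ait)
  # active with asthma: may still discontinue; asthma absorbing
  P["active_asthma", "dead"] <- pd1
  P["active_asthma", "discontinued_asthma"] <- (1 - pd1) * d
  P["active_asthma", "active_asthma"] <- (1 - pd1) * (1 - d)
  # discontinued / symptomatic-only: symptomatic asthma risk, no re-initiation
  for (s in c("discontinued", "symptomatic")) {
    sa <- paste0(s, "_asthma")
    P[s, "dead"] <- pd0
    P[s, sa] <- (1 - pd0) * pa_sym
    P[s, s] <- (1 - pd0) * (1 - pa_sym)
    P[sa, "dead"] <- pd1
    P[sa, sa] <- 1 - pd1
  }
  P["dead", "dead"] <- 1
  P
}

#' Propagate a cohort through the model
#'
#' Runs the full cohort (proportion 1 at entry) through `horizon_years`
#' annual cycles. Immunotherapy arms enter in the active (on-treatment)
#' regime; the symptomatic arm enters in the symptomatic-only regime. For
#' every cycle the trace records the start-of-cycle occupancy and the
#' half-cycle-corrected mid-cycle occupancy, defined per state as the
#' average of the cycle-start and cycle-end occupancies. All state-time
#' accruals (costs, QALYs, person-years) value the mid-cycle occupancy.
#'
#' @param arm An `arm_spec`.
#' @param clinical The `clinical` section of an `ait_config`.
#' @param settings The `settings` section of an `ait_config`.
#' @return A `cohort_trace`: list with matrices `start`, `end`, `mid`
#'   (cycles x states), the arm name, and the horizon.
#' @examples
#' cfg <- default_config()
#' tr <- run_cohort(cfg$arms$five_grass, cfg$clinical, cfg$settings)
#' head(as.data.frame(tr))
#' @export
run_cohort <- function(arm, clinical, settings) {
  H <- settings$horizon_years
  start <- end <- matrix(0, H, 7, dimnames = list(NULL, .states))
  entry <- if (identical(arm$name, "symptomatic")) "symptomatic" else "active"
  occ <- setNames(numeric(7), .states)
  occ[entry] <- 1
  for (t in seq_len(H)) {
    start[t, ] <- occ
    occ <- as.numeric(occ %*% transition_matrix(arm, clinical, t))
    names(occ) <- .states
    end[t, ] <- occ
  }
  trace <- list(start = start, end = end, mid = (start + end) / 2,
                arm = arm$name, horizon = H)
  class(trace) <- "cohort_trace"
  trace
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> arm '%s', %d annual cycles\n", x$arm, x$horizon))
  cat(sprintf("  mid-cycle active years: %.4f; final dead share: %.5f\n",
              sum(x$mid[, c("active", "active_asthma")]),
              x$end[x$horizon, "dead"]))
  invisible(x)
}

# Regime label of the reported trace: active regime is 'on_treatment' during
# the 3 treatment cycles and 'completed_treatment' afterwards.
.regime_label <- function(state, cycle) {
  base <- sub("_asthma$", "", state)
  if (base == "active") {
    if (cycle <= 3) "on_treatment" else "completed_treatment"
  } else if (base == "symptomatic") "symptomatic_only" else base
}

#' Tidy export of a cohort trace
#'
#' One row per cycle and state with start-of-cycle and mid-cycle occupancy.
#' States are reported with the regime labels `on_treatment` (active,
#' cycles 1--3), `completed_treatment` (active, cycles 4+), `discontinued`,
#' `symptomatic_only` and `dead`, plus an asthma flag.
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A data.frame with columns `cycle`, `state`, `asthma`,
#'   `start_occupancy`, `mid_occupancy`.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  rows <- expand.grid(state = .states, cycle = seq_len(x$horizon),
                      stringsAsFactors = FALSE)[, c("cycle", "state")]
  rows$asthma <- grepl("_asthma$", rows$state)
  rows$regime <- mapply(.regime_label, rows$state, rows$cycle)
  rows$start_occupancy <- x$start[cbind(rows$cycle, match(rows$state, .states))]
  rows$mid_occupancy <- x$mid[cbind(rows$cycle, match(rows$state, .states))]
  rows$state <- ifelse(rows$state == "dead", "dead", rows$regime)
  rows[, c("cycle", "state", "asthma", "start_occupancy", "mid_occupancy")]
}

# Mid-cycle occupancy aggregates used by the accumulators.
.mid_share <- function(trace, states) rowSums(trace$mid[, states, drop = FALSE])

trace_on_effect <- function(trace) .mid_share(trace, c("active", "active_asthma"))
trace_off_effect <- function(trace) {
  .mid_share(trace, c("discontinued", "discontinued_asthma",
                      "symptomatic", "symptomatic_asthma"))
}
trace_alive <- function(trace) trace_on_effect(trace) + trace_off_effect(trace)
trace_asthma <- function(trace) {
  .mid_share(trace, c("active_asthma", "discontinued_asthma", "symptomatic_asthma"))
}
# On-treatment = active regime during the treatment cycles only.
trace_on_treatment <- function(trace) {
  on <- trace_on_effect(trace)
  on[-seq_len(min(3, trace$horizon))] <- 0
  on
}

#' On-effect and off-effect person-years
#'
#' Splits the half-cycle-corrected alive person-years of a trace into years
#' spent with the immunotherapy effect (active regime: on treatment or
#' post-treatment with sustained effect) and years without it
#' (discontinued or symptomatic-only). The treatment effect observed during
#' the three treatment years is carried forward to the end of the horizon,
#' so for immunotherapy arms the on-effect share persists after cycle 3.
#'
#' @param trace A `cohort_trace`.
#' @param discount_rate Annual discount rate; 0 for undiscounted years.
#' @return A list with per-cycle vectors `on_effect`, `off_effect` and the
#'   scalars `on_effect_total`, `off_effect_total`.
#' @export
effect_person_years <- function(trace, discount_rate = 0) {
  d <- discount_factor(seq_len(trace$horizon), discount_rate)
  on <- trace_on_effect(trace) * d
  off <- trace_off_effect(trace) * d
  list(on_effect = on, off_effect = off,
       on_effect_total = sum(on), off_effect_total = sum(off))
}
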
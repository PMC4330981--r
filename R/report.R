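# Report writers. All files are plain CSV/JSON with undecorated decimal
# numbers; every run also writes a manifest (config hash, package version,
# seed, outputs) sufficient to reproduce it exactly.

config_hash <- function(config) {
  out <- unclass(config)
  out$arms <- lapply(out$arms, unclass)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  # Order-stable polynomial rolling hash over the canonical JSON (double
  # arithmetic stays exact below 2^53); no digest dependency needed.
  bytes <- as.integer(charToRaw(json))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(out_dir, config, outputs, seed = NULL) {
  manifest <- list(
    config_hash = config_hash(config),
    package_version = as.character(packageVersion("aitcea")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = outputs
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  out_dir
}

write_csv_plain <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the base-case report
#'
#' Runs the base case and writes `qalys.csv` (per-arm discounted and
#' undiscounted totals), `cost_components.csv` (per-arm undiscounted and
#' discounted component costs with column percentages),
#' `incrementals.csv`, `icers.csv` and `manifest.json`.
#'
#' @param config An `ait_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of files written.
#' @export
write_base_case_report <- function(config, out_dir) {
  .ensure_dir(out_dir)
  res <- run_base_case(config)
  qalys <- do.call(rbind, lapply(res$arms, function(a) {
    data.frame(arm = a$arm, qalys_discounted = a$qalys_discounted,
               qalys_undiscounted = a$qalys_undiscounted,
               cost_discounted = a$cost_discounted,
               cost_undiscounted = a$cost_undiscounted)
  }))
  comps <- do.call(rbind, lapply(res$arms, function(a) {
    cc <- a$costs
    tot <- cc$undiscounted[cc$component == "total"]
    data.frame(arm = a$arm, component = cc$component,
               undiscounted = cc$undiscounted, discounted = cc$discounted,
               percent = if (tot > 0) 100 * cc$undiscounted / tot else 0)
  }))
  inc <- res$incrementals
  icers <- inc[, c("reference", "comparator", "discounted", "icer", "icer_label")]
  files <- c("qalys.csv", "cost_components.csv", "incrementals.csv", "icers.csv")
  write_csv_plain(qalys, file.path(out_dir, "qalys.csv"))
  write_csv_plain(comps, file.path(out_dir, "cost_components.csv"))
  write_csv_plain(inc, file.path(out_dir, "incrementals.csv"))
  write_csv_plain(icers, file.path(out_dir, "icers.csv"))
  write_manifest(out_dir, config, files)
  invisible(file.path(out_dir, c(files, "manifest.json")))
}

#' Write the PSA report
#'
#' Runs the probabilistic sensitivity analysis and writes `scatter.csv`
#' (one row per draw with per-contrast incremental cost and QALYs),
#' `ceac.csv` (one row per threshold per arm), `psa_summary.json`
#' (percentile intervals, north-east-quadrant share, CEAC value at
#' EUR 20,000) and `manifest.json`.
#'
#' @param config Calibrated `ait_config`.
#' @param out_dir Output directory.
#' @param seed RNG seed (defaults to `config$settings$rng_seed`).
#' @param n_psa Number of draws (defaults to `config$settings$n_psa`).
#' @return Invisibly, the list of files written.
#' @export
write_psa_report <- function(config, out_dir, seed = NULL, n_psa = NULL) {
  .ensure_dir(out_dir)
  if (!is.null(seed)) config$settings$rng_seed <- seed
  if (!is.null(n_psa)) config$settings$n_psa <- n_psa
  psa <- run_psa(config)
  curve <- ceac(psa, config$settings$wtp_grid)
  scatter_cols <- grep("^(delta_cost|delta_qaly)_", names(psa$draws), value = TRUE)
  scatter <- cbind(draw = seq_len(psa$n), psa$draws[, scatter_cols])
  write_csv_plain(scatter, file.path(out_dir, "scatter.csv"))
  write_csv_plain(as.data.frame(curve), file.path(out_dir, "ceac.csv"))
  summ <- summary(psa)
  at20k <- curve[curve$wtp == 20000 & curve$arm == "five_grass", "probability"]
  summary_json <- list(
    n_draws = psa$n, n_failed = psa$n_failed, seed = config$settings$rng_seed,
    contrasts = summ,
    ceac_five_grass_at_20000 = if (length(at20k)) at20k else NA
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "psa_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_manifest(out_dir, config, c("scatter.csv", "ceac.csv", "psa_summary.json"),
                 seed = config$settings$rng_seed)
  invisible(file.path(out_dir, c("scatter.csv", "ceac.csv",
                                 "psa_summary.json", "manifest.json")))
}

#' Write the tornado (one-way DSA) report
#'
#' @param config Calibrated `ait_config`.
#' @param out_dir Output directory.
#' @param outcome Sort key passed to [univariate_dsa()].
#' @return Invisibly, the files written.
#' @export
write_dsa_report <- function(config, out_dir, outcome = "delta_qaly") {
  .ensure_dir(out_dir)
  tor <- univariate_dsa(config, outcome = outcome)
  write_csv_plain(tor, file.path(out_dir, "tornado.csv"))
  write_manifest(out_dir, config, "tornado.csv")
  invisible(file.path(out_dir, c("tornado.csv", "manifest.json")))
}

#' Write the scenario report
#'
#' @param config Calibrated `ait_config`.
#' @param out_dir Output directory.
#' @param scenarios Passed to [run_all_scenarios()].
#' @return Invisibly, the files written.
#' @export
write_scenario_report <- function(config, out_dir,
                                  scenarios = standard_scenarios()) {
  .ensure_dir(out_dir)
  rep <- run_all_scenarios(config, scenarios)
  write_csv_plain(rep, file.path(out_dir, "scenarios.csv"))
  write_manifest(out_dir, config, "scenarios.csv")
  invisible(file.path(out_dir, c("scenarios.csv", "manifest.json")))
}

#' Write the calibration report and patched configuration
#'
#' @param config Starting `ait_config`.
#' @param out_dir Output directory.
#' @return Invisibly, the files written (`calibration.json`,
#'   `calibrated_config.json`, `manifest.json`).
#' @export
write_calibration_report <- function(config, out_dir) {
  .ensure_dir(out_dir)
  cal <- calibrate_all(config)
  jsonlite::write_json(cal$report, file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_config(cal$config, file.path(out_dir, "calibrated_config.json"))
  write_manifest(out_dir, cal$config,
                 c("calibration.json", "calibrated_config.json"))
  invisible(file.path(out_dir, c("calibration.json", "calibrated_config.json",
                                 "manifest.json")))
}

#' Write the indirect-comparison report
#'
#' Pools trial summaries per class, forms the anchored contrast, and
#' writes `itc_pooled.json` plus a plain-text forest table
#' (`forest.txt`).
#'
#' @param trials Data.frame of trial summaries (see [read_trials_csv()]).
#' @param out_dir Output directory.
#' @param reference_sd,control_mean Back-transformation anchors for the
#'   pooled RTSS values.
#' @return Invisibly, the files written.
#' @export
write_itc_report <- function(trials, out_dir, reference_sd = 2.0,
                             control_mean = 4.47) {
  .ensure_dir(out_dir)
  pooled <- itc_pool(trials)
  as_row <- function(e) list(contrast = e$contrast, smd = e$smd, se = e$se,
                             ci_lower = e$ci_lower, ci_upper = e$ci_upper,
                             n_trials = e$n_trials,
                             rtss = to_rtss_scale(e, reference_sd, control_mean))
  jsonlite::write_json(
    list(pooled_a = as_row(pooled$pooled_a), pooled_b = as_row(pooled$pooled_b),
         indirect_contrast = as_row(pooled$contrast)),
    file.path(out_dir, "itc_pooled.json"), auto_unbox = TRUE, digits = NA
  )
  lines <- c(sprintf("%-22s %8s %8s %10s", "trial", "SMD", "var", "weight"))
  w <- 1 / pooled$per_trial$variance
  for (i in seq_len(nrow(pooled$per_trial))) {
    lines <- c(lines, sprintf("%-22s %8.3f %8.4f %9.1f%%",
                              pooled$per_trial$trial_id[i],
                              pooled$per_trial$smd[i],
                              pooled$per_trial$variance[i],
                              100 * w[i] / sum(w)))
  }
  for (e in list(pooled$pooled_a, pooled$pooled_b, pooled$contrast)) {
    lines <- c(lines, sprintf("%-22s %8.3f (95%% CI %.3f to %.3f)",
                              e$contrast, e$smd, e$ci_lower, e$ci_upper))
  }
  writeLines(lines, file.path(out_dir, "forest.txt"))
  invisible(file.path(out_dir, c("itc_pooled.json", "forest.txt")))
}
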
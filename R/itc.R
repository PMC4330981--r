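# Anchored indirect treatment comparison on standardized mean differences.
# Sign convention: SMD = (active mean - control mean) / pooled SD, so a
# negative SMD means symptom improvement over the common symptomatic /
# placebo comparator.

#' Standardized mean difference of one two-arm trial
#'
#' Cohen's d: `(mean_active - mean_control) / pooled SD`, with sampling
#' variance `(n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2))`. The small-sample
#' (Hedges) correction `J = 1 - 3 / (4 (n1 + n2) - 9)` is available as an
#' option and off by default.
#'
#' @param mean_active,sd_active,n_active Active-arm summary statistics.
#' @param mean_control,sd_control,n_control Control-arm summary statistics.
#' @param hedges Apply the small-sample correction.
#' @return Named list `smd`, `variance`.
#' @examples
#' smd(3.26, 2, 100, 4.47, 2, 100)   # smd -0.605
#' @export
smd <- function(mean_active, sd_active, n_active,
                mean_control, sd_control, n_control, hedges = FALSE) {
  if (n_active < 2 || n_control < 2) stop("arm sizes must be >= 2", call. = FALSE)
  if (sd_active <= 0 || sd_control <= 0) stop("arm SDs must be > 0", call. = FALSE)
  sp2 <- ((n_active - 1) * sd_active^2 + (n_control - 1) * sd_control^2) /
    (n_active + n_control - 2)
  if (sp2 <= 0) stop("zero pooled SD", call. = FALSE)
  d <- (mean_active - mean_control) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * (n_active + n_control) - 9))
  n <- n_active + n_control
  v <- n / (n_active * n_control) + d^2 / (2 * n)
  list(smd = d, variance = v)
}

#' Fixed-effect inverse-variance pooling
#'
#' Pools per-trial standardized mean differences with weights `1/variance`;
#' the pooled standard error is `(sum of weights)^-1/2`, so the pooled
#' variance never exceeds the smallest input variance and shrinks as trials
#' are added. Studies with small samples and wide uncertainty receive
#' correspondingly little weight.
#'
#' @param estimates List of `(smd, variance)` pairs (e.g. from [smd()]),
#'   or a data.frame with columns `smd` and `variance`.
#' @param contrast Label for the pooled contrast.
#' @return An `itc_estimate`: list with `smd`, `se`, `variance`,
#'   `ci_lower`, `ci_upper` (95%), `contrast`, `n_trials`.
#' @export
pool_fixed_effect <- function(estimates, contrast = "pooled") {
  if (is.data.frame(estimates)) {
    estimates <- lapply(seq_len(nrow(estimates)), function(i) {
      list(smd = estimates$smd[i], variance = estimates$variance[i])
    })
  }
  if (length(estimates) == 0) stop("no estimates to pool", call. = FALSE)
  g <- vapply(estimates, `[[`, 0, "smd")
  v <- vapply(estimates, `[[`, 0, "variance")
  if (any(v <= 0)) stop("variances must be > 0", call. = FALSE)
  w <- 1 / v
  pooled <- sum(w * g) / sum(w)
  se <- sqrt(1 / sum(w))
  out <- list(smd = pooled, se = se, variance = se^2,
              ci_lower = pooled - 1.959963984540054 * se,
              ci_upper = pooled + 1.959963984540054 * se,
              contrast = contrast, n_trials = length(estimates))
  class(out) <- "itc_estimate"
  out
}

#' @export
print.itc_estimate <- function(x, ...) {
  cat(sprintf("<itc_estimate> %s: SMD %.3f (SE %.3f, 95%% CI %.3f to %.3f, k = %d)\n",
              x$contrast, x$smd, x$se, x$ci_lower, x$ci_upper, x$n_trials))
  invisible(x)
}

#' Anchored indirect contrast of two treatments
#'
#' Bucher contrast of treatment A versus treatment B through their common
#' comparator: `smd_AB = smd_A - smd_B`, `var_AB = var_A + var_B`. Both
#' inputs must be anchored on the same comparator (checked via the
#' `anchor` attribute when present).
#'
#' @param a_vs_control,b_vs_control `itc_estimate` objects versus the
#'   common comparator.
#' @param contrast Label for the result.
#' @return An `itc_estimate` for A vs B.
#' @export
indirect_contrast <- function(a_vs_control, b_vs_control,
                              contrast = "A vs B (anchored)") {
  aa <- attr(a_vs_control, "anchor")
  ab <- attr(b_vs_control, "anchor")
  if (!is.null(aa) && !is.null(ab) && !identical(aa, ab)) {
    stop("mismatched anchors: '", aa, "' vs '", ab, "'", call. = FALSE)
  }
  se <- sqrt(a_vs_control$variance + b_vs_control$variance)
  out <- list(smd = a_vs_control$smd - b_vs_control$smd, se = se,
              variance = se^2,
              ci_lower = a_vs_control$smd - b_vs_control$smd - 1.959963984540054 * se,
              ci_upper = a_vs_control$smd - b_vs_control$smd + 1.959963984540054 * se,
              contrast = contrast,
              n_trials = a_vs_control$n_trials + b_vs_control$n_trials)
  class(out) <- "itc_estimate"
  out
}

#' Back-transform a pooled SMD to the symptom-score scale
#'
#' `rtss = control_mean + smd * reference_sd`. The inverse of the SMD
#' standardization against a chosen reference SD; with SMD 0 the control
#' mean is returned unchanged.
#'
#' @param pooled An `itc_estimate` (or a bare SMD).
#' @param reference_sd Reference standard deviation on the RTSS scale, > 0.
#' @param control_mean Common-comparator mean RTSS.
#' @return Pooled score on the RTSS scale.
#' @export
to_rtss_scale <- function(pooled, reference_sd, control_mean) {
  if (reference_sd <= 0) stop("reference_sd must be > 0", call. = FALSE)
  g <- if (inherits(pooled, "itc_estimate")) pooled$smd else pooled
  control_mean + g * reference_sd
}

#' Read trial summaries from CSV
#'
#' Expects columns `trial_id`, `class` (`five_grass`, `allergoid`,
#' `control`), `mean_active`, `sd_active`, `n_active`, `mean_control`,
#' `sd_control`, `n_control` -- one row per placebo-anchored trial.
#'
#' @param path CSV path.
#' @return A validated data.frame of trial summaries.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("trial_id", "class", "mean_active", "sd_active", "n_active",
              "mean_control", "sd_control", "n_control")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("trial CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$n_active < 2 | df$n_control < 2)) stop("arm sizes must be >= 2", call. = FALSE)
  if (any(df$sd_active <= 0 | df$sd_control <= 0)) stop("arm SDs must be > 0", call. = FALSE)
  df
}

#' Pool a set of anchored trials per class and form the indirect contrast
#'
#' Computes per-trial SMDs versus the common symptomatic/placebo
#' comparator, pools each treatment class by fixed-effect inverse-variance
#' weighting, and forms the anchored indirect contrast between the two
#' classes.
#'
#' @param trials Data.frame as returned by [read_trials_csv()].
#' @param class_a,class_b Treatment-class labels to contrast.
#' @param hedges Passed to [smd()].
#' @return List with `per_trial` (data.frame), pooled `itc_estimate`s for
#'   each class, and `contrast` (A vs B anchored).
#' @export
itc_pool <- function(trials, class_a = "five_grass", class_b = "allergoid",
                     hedges = FALSE) {
  per <- lapply(seq_len(nrow(trials)), function(i) {
    r <- trials[i, ]
    s <- smd(r$mean_active, r$sd_active, r$n_active,
             r$mean_control, r$sd_control, r$n_control, hedges = hedges)
    data.frame(trial_id = r$trial_id, class = r$class,
               smd = s$smd, variance = s$variance)
  })
  per <- do.call(rbind, per)
  pool_class <- function(cl) {
    est <- pool_fixed_effect(per[per$class == cl, c("smd", "variance")],
                             contrast = paste(cl, "vs control"))
    attr(est, "anchor") <- "control"
    est
  }
  a <- pool_class(class_a)
  b <- pool_class(class_b)
  list(per_trial = per, pooled_a = a, pooled_b = b,
       contrast = indirect_contrast(a, b,
                                    contrast = paste(class_a, "vs", class_b,
                                                     "(anchored)")))
}
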
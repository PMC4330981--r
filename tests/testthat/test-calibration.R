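cfg <- default_config()

test_that("utility-slope calibration matches its closed-form oracle", {
  k <- calibrate_utility_slope(cfg, target = 0.090)
  # oracle: target / (dRTSS * season fraction * on-effect person-years),
  # exact when asthma and mortality are off
  on_years <- effect_person_years(
    run_cohort(cfg$arms$five_grass, cfg$clinical, cfg$settings))$on_effect_total
  k_oracle <- 0.090 / ((4.47 - 3.26) * 0.25 * on_years)
  expect_lt(rel_err(k, k_oracle), 0.01)
  # the shipped default is this calibration
  expect_equal(cfg$utility$k_rtss_slope, k, tolerance = 1e-6)
  # degenerate and linearity properties
  expect_equal(calibrate_utility_slope(cfg, target = 0), 0)
  # linear up to the (tiny) survival-difference term at k = 0
  expect_equal(calibrate_utility_slope(cfg, target = 0.180), 2 * k,
               tolerance = 5e-4)
  # in the no-mortality limit the oracle is exact
  cfg0 <- no_mortality_config()
  k0 <- calibrate_utility_slope(cfg0, target = 0.090)
  on0 <- sum(closed_form_on_effect(0.29, 0.28))
  expect_equal(k0, 0.090 / (1.21 * 0.25 * on0), tolerance = 1e-8)
})

test_that("resource-count calibration inverts the published component totals", {
  counts <- calibrate_resource_counts(cfg)
  # independent linear oracles
  ey_al <- effect_person_years(
    run_cohort(cfg$arms$allergoid, cfg$clinical, cfg$settings))
  on_trt_al <- sum(ey_al$on_effect[1:3])   # injections accrue on treatment only
  expect_lt(rel_err(counts$injections_per_treatment_year[["allergoid"]],
                    69 / (5.11 * on_trt_al)), 0.01)
  expect_lt(rel_err(counts$visits_per_treatment_year[["five_grass"]], 3.4), 0.02)
  expect_lt(rel_err(counts$visits_per_treatment_year[["allergoid"]], 5.1), 0.02)
  # shipped defaults are these calibrations
  expect_equal(cfg$arms$five_grass$visits_per_treatment_year,
               counts$visits_per_treatment_year[["five_grass"]],
               tolerance = 1e-6)
  expect_equal(cfg$arms$allergoid$injections_per_treatment_year,
               counts$injections_per_treatment_year[["allergoid"]],
               tolerance = 1e-6)
  # zero target gives zero count
  z <- calibrate_resource_counts(
    cfg, targets = list(visits_five_grass = 267, visits_allergoid = 299,
                        injection_allergoid = 0))
  expect_equal(z$injections_per_treatment_year[["allergoid"]], 0)
  # a target below the off-treatment visit floor is flagged as inconsistent
  expect_error(
    calibrate_resource_counts(
      cfg, targets = list(visits_five_grass = 10, visits_allergoid = 299,
                          injection_allergoid = 69)),
    "calibration error")
})

test_that("productivity-saving calibration matches the linear oracle and its cross-check", {
  ps <- calibrate_productivity_saving(cfg)
  base <- run_base_case(cfg)
  d_on <- effect_person_years(base$arms$five_grass$trace, 0.03)$on_effect_total -
    effect_person_years(base$arms$symptomatic$trace, 0.03)$on_effect_total
  payer <- base$incrementals
  payer_dc <- payer$delta_cost[payer$comparator == "symptomatic" & payer$discounted]
  expect_equal(ps, (payer_dc - 784) / d_on, tolerance = 1e-9)
  # about 4.3 labour hours per season at the published hourly cost
  expect_equal(ps / cfg$costs$c_labour_hour, 4.3, tolerance = 0.1)
  # zero saving: societal equals payer incremental cost
  cfg0 <- cfg
  cfg0$costs$productivity_saving_per_season <- 0
  cfg0$settings$perspective <- "societal"
  soc <- run_base_case(cfg0)$incrementals
  expect_equal(soc$delta_cost[soc$comparator == "symptomatic" & soc$discounted],
               payer_dc, tolerance = 1e-9)
})

test_that("baseline-utility calibration reproduces the published absolute QALY levels", {
  u0 <- calibrate_baseline_utility(cfg, target = 7.235)
  expect_equal(cfg$utility$u_baseline, u0, tolerance = 1e-6)
  cfg2 <- cfg
  cfg2$utility$u_baseline <- u0
  expect_equal(run_arm(cfg2, "symptomatic")$qalys_discounted, 7.235,
               tolerance = 1e-9)
  # held out: the AIT arms' absolute levels follow
  expect_lt(rel_err(run_arm(cfg2, "five_grass")$qalys_discounted, 7.316), 0.001)
  expect_lt(rel_err(run_arm(cfg2, "allergoid")$qalys_discounted, 7.280), 0.001)
  # with zero decrements, a target of the discounted person-year sum gives 1
  cfg1 <- no_mortality_config()
  cfg1$utility$k_rtss_slope <- 0
  u1 <- calibrate_baseline_utility(cfg1, target = sum(1.03^-(0:8)))
  expect_equal(u1, 1, tolerance = 1e-7)
})

test_that("calibrations are self-consistent and mutually independent", {
  cal <- calibrate_all(cfg)
  expect_true(all(abs(cal$report$residual / cal$report$printed) < 0.005))
  # triangular system: recalibrating the slope does not move the cost targets
  cfg2 <- cal$config
  cfg2$utility$k_rtss_slope <- cfg2$utility$k_rtss_slope * 2
  counts2 <- calibrate_resource_counts(cfg2)
  expect_equal(counts2$visits_per_treatment_year[["five_grass"]],
               cal$config$arms$five_grass$visits_per_treatment_year,
               tolerance = 1e-9)
})
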
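cfg <- default_config()

test_that("discounting values the first model year undiscounted", {
  expect_equal(discount_factor(1, 0.03), 1)
  expect_equal(discount_factor(2, 0.03), 1 / 1.03)
  expect_equal(discount_factor(5, 0), 1)
  expect_equal(discount_factor(1:9, 0.03), 1.03^-(0:8))
  expect_error(discount_factor(0, 0.03), "cycle")
  expect_error(discount_factor(1, -0.1), "rate")
})

test_that("state utilities apply the seasonal symptom decrement by regime", {
  u <- cfg$utility
  u$k_rtss_slope <- 0.0590
  dec <- u$u_baseline - cycle_utility("symptomatic", cfg$arms$five_grass, u)
  expect_equal(dec, 0.25 * 0.0590 * 4.47, tolerance = 1e-12)
  # on effect, the arm's own score applies
  dec_on <- u$u_baseline - cycle_utility("active", cfg$arms$five_grass, u)
  expect_equal(dec_on, 0.25 * 0.0590 * 3.26, tolerance = 1e-12)
  # zero slope: baseline utility for all alive non-asthmatic states
  u0 <- u; u0$k_rtss_slope <- 0
  for (s in c("active", "discontinued", "symptomatic")) {
    expect_equal(cycle_utility(s, cfg$arms$five_grass, u0), u$u_baseline)
  }
  expect_equal(cycle_utility("dead", cfg$arms$five_grass, u), 0)
  # asthma decrement subtracts on top
  ua <- u; ua$asthma_decrement <- 0.1
  expect_equal(cycle_utility("active", cfg$arms$five_grass, ua, asthma = TRUE),
               cycle_utility("active", cfg$arms$five_grass, ua) - 0.1)
  # pathological parameters clamp at zero with a warning
  ub <- u; ub$u_baseline <- 0.01; ub$k_rtss_slope <- 0.2
  expect_warning(val <- cycle_utility("symptomatic", cfg$arms$five_grass, ub),
                 "clamped")
  expect_equal(val, 0)
})

test_that("undiscounted cost components reproduce the published 9-year totals", {
  res <- run_base_case(cfg)
  comp <- function(arm, component) {
    cc <- res$arms[[arm]]$costs
    cc$undiscounted[cc$component == component]
  }
  # symptomatic arm: pure off-treatment schedule
  expect_equal(comp("symptomatic", "visits"), 9 * 1.9 * 13.29, tolerance = 0.01)
  expect_equal(comp("symptomatic", "other_drugs"), 9 * (7.54 + 3.83),
               tolerance = 0.01)
  expect_equal(comp("symptomatic", "treatment"), 0)
  expect_equal(comp("symptomatic", "injection_control"), 0)
  expect_equal(comp("symptomatic", "diagnostics"), 0)
  # AIT arms: published component cells
  expect_lt(rel_err(comp("five_grass", "other_drugs"), 82), 0.01)
  expect_lt(rel_err(comp("five_grass", "injection_control"), 4), 0.10)
  expect_equal(comp("five_grass", "diagnostics"), 20.61)
  expect_equal(comp("allergoid", "diagnostics"), 20.61)
  expect_lt(rel_err(comp("allergoid", "other_drugs"), 86), 0.01)
  expect_lt(rel_err(comp("symptomatic", "asthma"), 34), 0.02)
})

test_that("cost breakdowns are additive, non-negative, and discount-monotone", {
  for (arm_name in names(cfg$arms)) {
    res <- run_arm(cfg, arm_name)
    cc <- res$costs
    comps <- cc[cc$component != "total", ]
    tot <- cc[cc$component == "total", ]
    expect_equal(sum(comps$undiscounted), tot$undiscounted, tolerance = 1e-9)
    expect_equal(sum(comps$discounted), tot$discounted, tolerance = 1e-9)
    expect_true(all(comps$undiscounted >= 0))
    expect_true(all(comps$discounted <= comps$undiscounted + 1e-12))
  }
  # equality of discounted and undiscounted iff rate = 0
  cfg0 <- cfg
  cfg0$settings$discount_rate <- 0
  cc0 <- run_arm(cfg0, "five_grass")$costs
  expect_equal(cc0$discounted, cc0$undiscounted)
})

test_that("treatment cost equals the closed-form persistence oracle in the zero-mortality limit", {
  cfg0 <- no_mortality_config()
  for (arm_name in c("five_grass", "allergoid")) {
    arm <- cfg0$arms[[arm_name]]
    cc <- run_arm(cfg0, arm_name)$costs
    on_years <- sum(closed_form_on_effect(arm$disc_y1, arm$disc_y2)[1:3])
    expect_equal(cc$undiscounted[cc$component == "treatment"],
                 annual_drug_cost(arm, cfg0$utility$season_months) * on_years,
                 tolerance = 1e-9)
  }
})

test_that("productivity costs appear only under the societal perspective", {
  soc <- cfg
  soc$settings$perspective <- "societal"
  cc_payer <- run_arm(cfg, "symptomatic")$costs
  cc_soc <- run_arm(soc, "symptomatic")$costs
  expect_equal(cc_payer$undiscounted[cc_payer$component == "productivity"], 0)
  expect_gt(cc_soc$undiscounted[cc_soc$component == "productivity"], 0)
  # all other components unchanged
  other <- cc_soc$component != "productivity" & cc_soc$component != "total"
  expect_equal(cc_soc$undiscounted[other], cc_payer$undiscounted[other])
})

test_that("symptom-driven QALY differences scale linearly with the season length", {
  dq_at <- function(m) {
    c0 <- no_mortality_config()
    c0$utility$season_months <- m
    run_arm(c0, "five_grass")$qalys_undiscounted -
      run_arm(c0, "symptomatic")$qalys_undiscounted
  }
  base <- dq_at(3)
  expect_equal(dq_at(1.5), base / 2, tolerance = 1e-12)
  expect_equal(dq_at(6), base * 2, tolerance = 1e-12)
})

test_that("QALY accumulation conserves time in the decrement-free limit", {
  cfg0 <- no_mortality_config()
  cfg0$utility$u_baseline <- 1
  cfg0$utility$k_rtss_slope <- 0
  q <- run_arm(cfg0, "five_grass")
  expect_equal(q$qalys_undiscounted, 9, tolerance = 1e-12)
  expect_equal(q$qalys_discounted, sum(1.03^-(0:8)), tolerance = 1e-12)
})

test_that("incremental comparison handles ICERs, dominance and net benefit consistently", {
  mk <- function(dc, de) {
    ref <- list(arm = "a", cost_discounted = dc, qalys_discounted = de,
                cost_undiscounted = dc, qalys_undiscounted = de)
    cmpr <- list(arm = "b", cost_discounted = 0, qalys_discounted = 0,
                 cost_undiscounted = 0, qalys_undiscounted = 0)
    compare_arms(ref, cmpr)
  }
  expect_equal(mk(100, 0.01)$icer, 10000)
  expect_equal(mk(-10, 0.01)$icer, "dominant")
  expect_equal(mk(10, -0.01)$icer, "dominated")
  expect_equal(mk(10, 0)$icer, "undefined")
  expect_equal(mk(10, 0)$nmb, -10)
  # NMB sign flips exactly at the ICER
  cmp <- compare_arms(run_arm(cfg, "five_grass"), run_arm(cfg, "allergoid"))
  icer <- cmp$icer
  below <- compare_arms(run_arm(cfg, "five_grass"), run_arm(cfg, "allergoid"),
                        wtp = icer * 0.999)
  above <- compare_arms(run_arm(cfg, "five_grass"), run_arm(cfg, "allergoid"),
                        wtp = icer * 1.001)
  at <- compare_arms(run_arm(cfg, "five_grass"), run_arm(cfg, "allergoid"),
                     wtp = icer)
  expect_lt(below$nmb, 0)
  expect_gt(above$nmb, 0)
  expect_equal(at$nmb, 0, tolerance = 1e-6)
})
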
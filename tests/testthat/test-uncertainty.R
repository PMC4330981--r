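cfg <- default_config()

test_that("distribution building assigns the stated families with moment-matched shapes", {
  d <- build_distributions(cfg)
  d1 <- d[["arms.five_grass.disc_y1"]]
  expect_equal(d1$family, "beta")
  expect_equal(d1$se, 0.058)
  # method-of-moments identity: alpha / (alpha + beta) = mean
  expect_equal(unname(d1$shapes["shape1"] / sum(d1$shapes)), 0.29,
               tolerance = 1e-9)
  dv <- d[["costs.c_specialist_visit"]]
  expect_equal(dv$family, "gamma")
  expect_equal(dv$se, 2.658)
  expect_equal(unname(dv$shapes["shape"] / dv$shapes["rate"]), 13.29,
               tolerance = 1e-9)
  dr <- d[["clinical.rr_asthma_ait"]]
  expect_equal(dr$family, "normal")
  expect_equal(dr$se, 0.101)
  # efficacy parameters are normal on the RTSS differences
  de <- d[["efficacy.five_grass"]]
  expect_equal(de$family, "normal")
  expect_equal(de$mean, 3.26 - 4.47)
  expect_equal(de$se, cfg$settings$efficacy_se_scale * 1.21, tolerance = 1e-9)
  expect_equal(d[["utility.season_months"]]$family, "gamma")
  # infeasible beta (se too large for the mean) errors with the parameter named
  bad <- cfg
  bad$clinical$p_asthma_symptomatic <- 0.999
  expect_error(build_distributions(bad), "p_asthma_symptomatic")
})

test_that("sampling is seed-reproducible and respects supports", {
  d <- build_distributions(cfg)
  m1 <- sample_psa(d, 200, seed = 5)
  m2 <- sample_psa(d, 200, seed = 5)
  expect_identical(m1, m2)
  m3 <- sample_psa(d, 200, seed = 6)
  expect_false(identical(m1, m3))
  beta_cols <- names(d)[vapply(d, `[[`, "", "family") == "beta"]
  expect_true(all(m1[, beta_cols] >= 0 & m1[, beta_cols] <= 1))
  gamma_cols <- names(d)[vapply(d, `[[`, "", "family") == "gamma"]
  expect_true(all(m1[, gamma_cols] >= 0))
  expect_true(all(m1[, "utility.season_months"] <= 12))
  # sample means converge to the input means (3 MC SEs at n = 1000)
  m <- sample_psa(d, 1000, seed = 2)
  for (nm in c("arms.five_grass.disc_y1", "costs.c_specialist_visit",
               "clinical.rr_asthma_ait")) {
    mc_se <- d[[nm]]$se / sqrt(1000)
    expect_lt(abs(mean(m[, nm]) - d[[nm]]$mean), 3 * mc_se)
  }
})

test_that("degenerate-variance PSA collapses exactly to the deterministic base case", {
  d <- build_distributions(cfg)
  for (nm in names(d)) d[[nm]]$se <- 0
  draws <- sample_psa(d, 5, seed = 1)
  psa <- run_psa(cfg, draws, d)
  base <- run_base_case(cfg)
  inc <- base$incrementals
  dc_base <- inc$delta_cost[inc$comparator == "allergoid" & inc$discounted]
  dq_base <- inc$delta_qaly[inc$comparator == "allergoid" & inc$discounted]
  expect_equal(psa$draws$delta_cost_vs_allergoid, rep(dc_base, 5),
               tolerance = 1e-12)
  expect_equal(psa$draws$delta_qaly_vs_allergoid, rep(dq_base, 5),
               tolerance = 1e-12)
})

test_that("PSA incremental outcomes are centred on the base case", {
  psa <- suppressWarnings(run_psa(cfg, sample_psa(build_distributions(cfg),
                                                  400, seed = 3)))
  expect_equal(psa$n_failed, 0)
  base <- run_base_case(cfg)
  inc <- base$incrementals
  dq_base <- inc$delta_qaly[inc$comparator == "allergoid" & inc$discounted]
  dq <- psa$draws$delta_qaly_vs_allergoid
  mc_se <- sd(dq) / sqrt(length(dq))
  expect_lt(abs(mean(dq) - dq_base), 3 * mc_se + 0.002)
  # summary reports coherent percentile intervals
  s <- summary(psa)
  expect_true(all(s$ci_low_qaly <= s$mean_delta_qaly &
                    s$mean_delta_qaly <= s$ci_high_qaly))
})

test_that("acceptability curves are proper probabilities with the cheapest arm winning at zero WTP", {
  psa <- suppressWarnings(run_psa(cfg, sample_psa(build_distributions(cfg),
                                                  300, seed = 4)))
  cv <- ceac(psa, c(0, 10000, 20000, 50000))
  sums <- tapply(cv$probability, cv$wtp, sum)
  expect_equal(as.vector(sums), rep(1, 4), tolerance = 1e-12)
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
  # lambda = 0: probability of being cheapest
  at0 <- cv[cv$wtp == 0, ]
  cheapest <- apply(psa$draws[, paste0("cost_", psa$arms)], 1, which.min)
  expect_equal(at0$probability[at0$arm == "symptomatic"],
               mean(cheapest == 3))
  # two-arm restriction sums to one as well
  cv2 <- ceac(psa, 20000, arms = c("five_grass", "allergoid"))
  expect_equal(sum(cv2$probability), 1, tolerance = 1e-12)
})

test_that("the tornado ranks efficacy first for QALYs and season length first for costs", {
  tq <- univariate_dsa(cfg, outcome = "delta_qaly")
  expect_equal(tq$parameter[1], "efficacy.five_grass")
  tc <- univariate_dsa(cfg, outcome = "delta_cost")
  expect_equal(tc$parameter[1], "utility.season_months")
  # a zero-variance parameter produces a zero output range
  d <- build_distributions(cfg)
  d <- d["costs.c_diagnostics"]
  d$costs.c_diagnostics$se <- 0
  t0 <- univariate_dsa(cfg, distributions = d)
  expect_equal(t0$range, 0, tolerance = 1e-12)
  # base case lies between the bounds for a monotone parameter
  row <- tq[tq$parameter == "efficacy.five_grass", ]
  base <- run_base_case(cfg)$incrementals
  dq_base <- base$delta_qaly[base$comparator == "allergoid" & base$discounted]
  expect_true(min(row$delta_qaly_low, row$delta_qaly_high) <= dq_base &&
                dq_base <= max(row$delta_qaly_low, row$delta_qaly_high))
})
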
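cfg <- default_config()

test_that("transition matrices are row-stochastic with the published event probabilities", {
  for (arm in cfg$arms) {
    for (t in 1:9) {
      P <- transition_matrix(arm, cfg$clinical, t)
      expect_equal(unname(rowSums(P)), rep(1, 7), tolerance = 1e-14)
      expect_true(all(P >= 0 & P <= 1))
    }
  }
  P1 <- transition_matrix(cfg$arms$five_grass, cfg$clinical, 1)
  # cycle-1 discontinuation hazard 0.29 before the death/asthma splits
  disc_total <- P1["active", "discontinued"] + P1["active", "discontinued_asthma"]
  expect_equal(disc_total / (1 - cfg$clinical$p_death_all), 0.29)
  # no re-initiation after discontinuation, in any cycle
  P5 <- transition_matrix(cfg$arms$five_grass, cfg$clinical, 5)
  expect_equal(P5["discontinued", "active"], 0)
  expect_equal(P5["discontinued_asthma", "active_asthma"], 0)
  # symptomatic arm: asthma acquisition 0.0046 among survivors
  Ps <- transition_matrix(cfg$arms$symptomatic, cfg$clinical, 4)
  expect_equal(Ps["symptomatic", "symptomatic_asthma"] /
                 (1 - cfg$clinical$p_death_all), 0.0046)
  # dead is absorbing
  expect_equal(Ps["dead", "dead"], 1)
  expect_error(transition_matrix(cfg$arms$five_grass, cfg$clinical, 0), "cycle")
})

test_that("cohort traces conserve occupancy and the persistence pattern matches the discontinuation schedule", {
  tr <- run_cohort(cfg$arms$five_grass, cfg$clinical, cfg$settings)
  expect_equal(unname(rowSums(tr$start)), rep(1, 9), tolerance = 1e-12)
  expect_equal(unname(rowSums(tr$mid)), rep(1, 9), tolerance = 1e-12)
  expect_true(all(tr$start >= 0 & tr$start <= 1))
  # dead and asthma shares never decrease
  expect_true(all(diff(tr$start[, "dead"]) >= 0))
  ever_asthma <- rowSums(tr$start[, c("active_asthma", "discontinued_asthma",
                                      "symptomatic_asthma")])
  expect_true(all(diff(ever_asthma) > -1e-15))
  # start of cycle 2: 71% stayers net of first-cycle mortality
  on2 <- sum(tr$start[2, c("active", "active_asthma")])
  expect_equal(on2, 0.71 * (1 - 0.00046), tolerance = 1e-6)
  # mid-cycle on-treatment person-years over the 3 treatment cycles
  on_mid <- rowSums(tr$mid[, c("active", "active_asthma")])
  expect_equal(sum(on_mid[1:3]), 0.855 + 0.6106 + 0.5112, tolerance = 0.01)
  tr_al <- run_cohort(cfg$arms$allergoid, cfg$clinical, cfg$settings)
  on_mid_al <- rowSums(tr_al$mid[, c("active", "active_asthma")])
  expect_equal(sum(on_mid_al[1:3]), 0.795 + 0.4897 + 0.3894, tolerance = 0.01)
})

test_that("zero-mortality engine equals the closed-form persistence solution exactly", {
  cfg0 <- no_mortality_config()
  for (arm_name in c("five_grass", "allergoid")) {
    arm <- cfg0$arms[[arm_name]]
    tr <- run_cohort(arm, cfg0$clinical, cfg0$settings)
    expect_equal(unname(rowSums(tr$mid[, c("active", "active_asthma")])),
                 closed_form_on_effect(arm$disc_y1, arm$disc_y2),
                 tolerance = 1e-14)
  }
})

test_that("hand-enumerated 3-state miniature matches the engine to 1e-12", {
  # independent oracle: explicit per-year bookkeeping of stay/discontinue/
  # dead shares for an AIT arm without asthma
  cfg0 <- no_mortality_config()
  cfg0$clinical$p_death_all <- 0.01
  cfg0$clinical$p_death_asthma <- 0.01
  arm <- cfg0$arms$five_grass
  on <- 1; off <- 0; dead <- 0
  on_path <- off_path <- dead_path <- numeric(9)
  for (t in 1:9) {
    d <- if (t == 1) arm$disc_y1 else if (t == 2) arm$disc_y2 else 0
    new_dead <- (on + off) * 0.01
    new_off <- on * (1 - 0.01) * d + off * (1 - 0.01)
    new_on <- on * (1 - 0.01) * (1 - d)
    on_path[t] <- new_on; off_path[t] <- new_off; dead_path[t] <- dead + new_dead
    on <- new_on; off <- new_off; dead <- dead + new_dead
  }
  tr <- run_cohort(arm, cfg0$clinical, cfg0$settings)
  expect_equal(unname(tr$end[, "active"]), on_path, tolerance = 1e-12)
  expect_equal(unname(tr$end[, "discontinued"]), off_path, tolerance = 1e-12)
  expect_equal(unname(tr$end[, "dead"]), dead_path, tolerance = 1e-12)
})

test_that("with no discontinuation the arms differ only in labels and the asthma relative risk orders prevalence", {
  cfg0 <- default_config()
  cfg0$arms$five_grass$disc_y1 <- 0
  cfg0$arms$five_grass$disc_y2 <- 0
  tr_ait <- run_cohort(cfg0$arms$five_grass, cfg0$clinical, cfg0$settings)
  tr_sym <- run_cohort(cfg0$arms$symptomatic, cfg0$clinical, cfg0$settings)
  ait_states <- c("active", "active_asthma")
  sym_states <- c("symptomatic", "symptomatic_asthma")
  # regime labels aside, alive and dead shares track the same survival process
  expect_equal(unname(tr_ait$start[, "dead"]) <= unname(tr_sym$start[, "dead"]),
               rep(TRUE, 9))
  # rr < 1: asthma prevalence under AIT below symptomatic in every cycle
  expect_true(all(tr_ait$start[, "active_asthma"] <=
                    tr_sym$start[, "symptomatic_asthma"] + 1e-15))
})

test_that("effect person-years split on- and off-effect time and discount correctly", {
  tr <- run_cohort(cfg$arms$five_grass, cfg$clinical, cfg$settings)
  ey <- effect_person_years(tr)
  expect_equal(ey$on_effect_total, 1.977 + 6 * 0.5112, tolerance = 0.02)
  ey_d <- effect_person_years(tr, 0.03)
  expect_equal(ey_d$on_effect_total, 4.540, tolerance = 0.01)
  expect_lt(ey_d$on_effect_total, ey$on_effect_total)
  tr_sym <- run_cohort(cfg$arms$symptomatic, cfg$clinical, cfg$settings)
  expect_equal(effect_person_years(tr_sym)$on_effect_total, 0)
  # on + off = alive person-years
  expect_equal(ey$on_effect_total + ey$off_effect_total,
               sum(1 - tr$mid[, "dead"]), tolerance = 1e-12)
})

test_that("the tidy trace export labels regimes by cycle", {
  tr <- run_cohort(cfg$arms$five_grass, cfg$clinical, cfg$settings)
  df <- as.data.frame(tr)
  expect_setequal(unique(df$state[df$cycle == 1 & !df$asthma & df$state != "dead"]),
                  c("on_treatment", "discontinued", "symptomatic_only"))
  expect_true("completed_treatment" %in% df$state[df$cycle == 4])
  expect_false("on_treatment" %in% df$state[df$cycle == 4])
  # occupancy survives the relabelling
  expect_equal(sum(df$mid_occupancy[df$cycle == 5]), 1, tolerance = 1e-12)
})
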
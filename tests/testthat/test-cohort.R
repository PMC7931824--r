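p0 <- default_parameters()

test_that("strata weights cross avoidance and adherence independently", {
  s <- build_strata(p0, "CUC")
  expect_equal(s$weight, c(0.261, 0.739))
  expect_equal(sum(s$weight), 1)

  s <- build_strata(p0, "TM")
  expect_equal(sum(s$weight), 1)
  expect_equal(s$weight[s$avoider & s$adherent], 0.261 * 0.80)
  expect_equal(s$weight[!s$avoider & !s$adherent], 0.739 * 0.20)

  p <- p0; p$avoidance <- 0
  s <- build_strata(p, "TM")
  expect_equal(sum(s$weight), 1)
  expect_equal(sum(s$weight[s$avoider]), 0)
})

test_that("event probabilities reflect avoidance and telemonitoring", {
  expect_equal(effective_event_probabilities(p0, FALSE, FALSE, "CUC", 0),
               c(p_hosp = 0.0296, p_death = 0.0279))
  # avoiders lose the multidisciplinary-care benefit while avoidance lasts
  expect_equal(effective_event_probabilities(p0, TRUE, FALSE, "CUC", 0),
               c(p_hosp = 0.0296 / 0.74, p_death = 0.0279 / 0.75))
  # window expired at cycle 18 (1.5 years)
  expect_equal(effective_event_probabilities(p0, TRUE, FALSE, "CUC", 18),
               c(p_hosp = 0.0296, p_death = 0.0279))
  # telemonitoring acts on adherent avoiders, inside the window ...
  expect_equal(effective_event_probabilities(p0, TRUE, TRUE, "TM", 0),
               c(p_hosp = 0.0296 / 0.74 * 0.5,
                 p_death = 0.0279 / 0.75 * 0.81))
  # ... and after it
  expect_equal(effective_event_probabilities(p0, TRUE, TRUE, "TM", 18),
               c(p_hosp = 0.0148, p_death = 0.022599))
  # non-avoiders keep clinic care; telemonitoring changes nothing for them
  expect_equal(effective_event_probabilities(p0, FALSE, TRUE, "TM", 0),
               c(p_hosp = 0.0296, p_death = 0.0279))
  # division past 1 clamps with a warning
  p <- p0; p$rr_death_mdc <- 0.01
  expect_warning(
    pr <- effective_event_probabilities(p, TRUE, FALSE, "CUC", 0),
    "clamped")
  expect_equal(unname(pr["p_death"]), 1)
})

test_that("cycle transition applies competing death then NYHA movement", {
  occ <- c(1, 0, 0, 0, 0)
  expect_equal(unname(cycle_transition(occ, p0$transition, 0)),
               c(0.9597, 0.0394, 0.0009, 0, 0))
  expect_equal(unname(cycle_transition(occ, p0$transition, 1)),
               c(0, 0, 0, 0, 1))
  # brute-force enumeration over death/transition branches
  occ <- c(0.5, 0.5, 0, 0, 0)
  expect_equal(unname(cycle_transition(occ, p0$transition, 0.1)),
               naive_cycle_enum(occ, p0$transition, 0.1))
  for (i in 1:10) {
    set.seed(i)
    occ <- stats::runif(5); occ <- occ / sum(occ)
    pd <- stats::runif(1)
    got <- cycle_transition(occ, p0$transition, pd)
    expect_equal(unname(got), naive_cycle_enum(occ, p0$transition, pd))
    expect_equal(sum(got), sum(occ), tolerance = 1e-12)
  }
  bad <- p0$transition; bad[1, 1] <- 0.9
  expect_error(cycle_transition(c(1, 0, 0, 0, 0), bad, 0),
               "row-stochastic")
})

test_that("cycle accrual follows the cost and utility arithmetic", {
  cfg <- analysis_config()
  zero <- accrue_cycle(c(0, 0, 0, 0, 1), p0, "CUC", 0.0296, 0.0279, 0, cfg)
  expect_equal(zero$discounted_cost, 0)
  expect_equal(zero$discounted_qaly, 0)

  a1 <- accrue_cycle(c(1, 0, 0, 0, 0), p0, "CUC", 0, 0, 0, cfg)
  expect_equal(a1$discounted_cost, 197)
  expect_equal(a1$discounted_qaly, 0.82 / 12)

  # class IV, certain hospitalization: disutility and admission costs
  a2 <- accrue_cycle(c(0, 0, 0, 1, 0), p0, "CUC", 1, 0, 0, cfg)
  expect_equal(a2$discounted_qaly, (0.46 - 0.29) / 12)
  expect_equal(a2$discounted_cost, 197 + 654 * 8)

  # every death incurs one terminal admission
  a3 <- accrue_cycle(c(1, 0, 0, 0, 0), p0, "CUC", 0, 0.1, 0, cfg)
  expect_equal(a3$discounted_cost, 197 + 0.1 * 654 * 8)

  # telemonitoring fee and discounting at cycle 12
  a4 <- accrue_cycle(c(1, 0, 0, 0, 0), p0, "TM", 0, 0, 12, cfg,
                     tm_fee = TRUE)
  expect_equal(a4$discounted_cost, (197 + 50) / 1.03)
  expect_equal(a4$discounted_qaly, 0.82 / 12 / 1.03)
})

test_that("cohort run matches a hand-computed one-cycle case", {
  p <- p0
  p$avoidance <- 0
  p$init_nyha[] <- c(0, 1, 0, 0)
  cfg <- analysis_config(horizon_years = 1 / 12,
                         half_cycle_correction = FALSE)
  run <- run_cohort(p, "CUC", cfg)
  expect_equal(nrow(run$trace), 1)
  expect_equal(run$total_cost,
               197 + (0.0296 + 0.0279) * 654 * 8)
  expect_equal(run$total_qaly, (0.74 - 0.0296 * 0.07) / 12)

  # zero horizon: nothing accrues but the telemonitoring setup cost
  cfg0 <- analysis_config(horizon_years = 0)
  expect_equal(run_cohort(p, "CUC", cfg0)$total_cost, 0)
  expect_equal(run_cohort(p, "TM", cfg0)$total_cost, 80)
  expect_equal(run_cohort(p, "TM", cfg0)$total_qaly, 0)
})

test_that("fast engine agrees with composing the exported primitives", {
  # re-simulate one stratum with the elementary operations and compare
  # against the engine trace (guards the optimized inner loop)
  p <- p0
  cfg <- analysis_config(horizon_years = 2, half_cycle_correction = FALSE)
  for (strategy in c("CUC", "TM")) {
    run <- run_cohort(p, strategy, cfg)
    strata <- build_strata(p, strategy)
    cost <- qaly <- numeric(24)
    for (s in seq_len(nrow(strata))) {
      occ <- c(strata$weight[s] * p$init_nyha, 0)
      for (t in 0:23) {
        pr <- effective_event_probabilities(p, strata$avoider[s],
                                            isTRUE(strata$adherent[s]),
                                            strategy, t)
        acc <- accrue_cycle(occ, p, strategy, pr[["p_hosp"]],
                            pr[["p_death"]], t, cfg,
                            tm_fee = strategy == "TM" && strata$avoider[s])
        cost[t + 1] <- cost[t + 1] + acc$discounted_cost
        qaly[t + 1] <- qaly[t + 1] + acc$discounted_qaly
        occ <- cycle_transition(occ, p$transition, pr[["p_death"]])
      }
    }
    expect_equal(run$trace$discounted_cost, cost)
    expect_equal(run$trace$discounted_qaly, qaly)
  }
})

test_that("mass is conserved and mortality is monotone every cycle", {
  cfg <- analysis_config()
  for (strategy in c("CUC", "TM")) {
    run <- run_cohort(p0, strategy, cfg)
    occ <- as.matrix(run$trace[, c("I", "II", "III", "IV", "Dead")])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(occ >= -1e-15))
    expect_true(all(diff(run$trace$alive_mass) <= 1e-12))
  }
})

test_that("a null intervention makes the two arms identical", {
  p <- p0
  p$rr_hosp_tm <- 1
  p$rr_death_tm <- 1
  p$tm_setup_cost <- 0
  p$tm_monthly_cost <- 0
  cfg <- analysis_config()
  cuc <- run_cohort(p, "CUC", cfg)
  tm <- run_cohort(p, "TM", cfg)
  expect_equal(tm$total_cost, cuc$total_cost, tolerance = 1e-12)
  expect_equal(tm$total_qaly, cuc$total_qaly, tolerance = 1e-12)
  expect_equal(tm$trace$alive_mass, cuc$trace$alive_mass,
               tolerance = 1e-12)
})

test_that("discounting and avoidance-duration invariants hold", {
  cfg0 <- analysis_config(discount_rate_annual = 0)
  cfg3 <- analysis_config()
  r0 <- run_cohort(p0, "CUC", cfg0)
  r3 <- run_cohort(p0, "CUC", cfg3)
  expect_lt(r3$total_cost, r0$total_cost)
  expect_lt(r3$total_qaly, r0$total_qaly)
  # with no discounting, totals are plain sums of undiscounted accruals
  expect_equal(r0$total_qaly,
               sum(r0$trace$discounted_qaly))

  p <- p0; p$avoidance <- 0
  runs <- lapply(c(0.5, 1.5, 2), function(d) {
    p$avoidance_duration_years <- d
    run_cohort(p, "CUC", cfg3)
  })
  expect_equal(runs[[1]]$total_cost, runs[[2]]$total_cost)
  expect_equal(runs[[2]]$total_qaly, runs[[3]]$total_qaly)
})

test_that("half-cycle correction lowers accrual relative to start-of-cycle", {
  on <- run_cohort(p0, "CUC", analysis_config())
  off <- run_cohort(p0, "CUC",
                    analysis_config(half_cycle_correction = FALSE))
  eoc <- run_cohort(p0, "CUC",
                    analysis_config(half_cycle_correction = FALSE,
                                    accrual_timing = "end_of_cycle"))
  expect_lt(on$total_qaly, off$total_qaly)
  expect_gt(on$total_qaly, eoc$total_qaly)
  expect_equal(on$total_qaly, (off$total_qaly + eoc$total_qaly) / 2,
               tolerance = 1e-9)
})
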
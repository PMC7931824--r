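test_that("base-case values match the published parameter table", {
  p <- default_parameters()
  expect_equal(p$p_hosp_mdc, 0.0296)
  expect_equal(p$p_death_mdc, 0.0279)
  expect_equal(unname(p$init_nyha), c(0.09, 0.44, 0.34, 0.13))
  expect_equal(unname(p$transition["I", ]), c(0.9597, 0.0394, 0.0009, 0))
  expect_equal(sum(p$transition["I", ]), 1)
  expect_equal(unname(p$transition["IV", ]),
               c(0.0010, 0.0443, 0.8515, 0.1032))
  expect_equal(unname(p$utility), c(0.82, 0.74, 0.64, 0.46))
  expect_equal(unname(p$disutility_hosp), c(0.04, 0.07, 0.10, 0.29))
  expect_equal(c(p$rr_hosp_mdc, p$rr_death_mdc), c(0.74, 0.75))
  expect_equal(c(p$rr_hosp_tm, p$rr_death_tm), c(0.50, 0.81))
  expect_equal(c(p$cost_hosp_day, p$los_days, p$cost_outpatient_month),
               c(654, 8, 197))
  expect_equal(c(p$tm_setup_cost, p$tm_monthly_cost), c(80, 50))
  expect_equal(c(p$adherence, p$avoidance, p$avoidance_duration_years),
               c(0.80, 0.261, 1.5))
})

test_that("defaults validate cleanly and violations are reported as data", {
  expect_identical(validate_parameters(default_parameters()), character(0))

  p <- default_parameters()
  p$utility["IV"] <- 1.2
  v <- validate_parameters(p)
  expect_length(v, 1)
  expect_match(v, "utility")

  p <- default_parameters()
  p$cost_hosp_day <- -5
  v <- validate_parameters(p)
  expect_length(v, 1)
  expect_match(v, "cost_hosp_day")

  p <- default_parameters()
  p$transition[2, 2] <- p$transition[2, 2] - 0.1
  v <- validate_parameters(p)
  expect_match(v[1], "row II")
})

test_that("specification table is internally consistent", {
  sp <- parameter_specs()
  expect_true(all(sp$low <= sp$base & sp$base <= sp$high))
  nonfixed <- sp$low < sp$high
  # every parameter with a real range has high > low
  expect_true(all(sp$high[nonfixed] > sp$low[nonfixed]))
  expect_true(all(sp$family %in% c("dirichlet_row", "beta", "lognormal_rr",
                                   "triangular", "uniform", "gamma",
                                   "fixed")))
  beta_dir <- sp$family %in% c("beta", "dirichlet_row")
  expect_true(all(sp$low[beta_dir] >= 0 & sp$high[beta_dir] <= 1))
  expect_true(all(sp$low[sp$family == "gamma"] >= 0))
  # one row per elementary input: 4 init + 16 transition + 8 utility-side
  # + 14 scalars
  expect_identical(nrow(sp), 42L)
})

test_that("JSON configuration round-trips and overrides defaults", {
  expect_equal(load_parameters("{}")$params, default_parameters())

  pc <- load_parameters('{"tm_monthly_cost": 60}')
  expect_equal(pc$params$tm_monthly_cost, 60)
  pc$params$tm_monthly_cost <- 50
  expect_equal(pc$params, default_parameters())

  # full round-trip, field for field
  p <- default_parameters()
  p$avoidance <- 0.3
  p$transition[1, 1:2] <- c(0.96, 0.0391)
  js <- serialize_parameters(p)
  expect_equal(load_parameters(js)$params, p)

  expect_error(load_parameters('{"not_a_field": 1}'), "unknown")
  expect_error(
    load_parameters('{"transition": [[0.8,0.1,0,0],[0.0073,0.9877,0.0039,0.0011],[0.001,0.0443,0.8843,0.0704],[0.001,0.0443,0.8515,0.1032]]}'),
    "row I")
  expect_error(load_parameters('{"broken'), "parse")
})

test_that("analysis settings carry the published analysis defaults", {
  cfg <- analysis_config()
  expect_equal(cfg$horizon_years, 10)
  expect_equal(cfg$discount_rate_annual, 0.03)
  expect_equal(cfg$wtp, 48937)
  expect_equal(cfg$psa_iterations, 10000L)
  expect_error(analysis_config(horizon_years = -1))
  cfg2 <- load_parameters('{"config": {"wtp": 30000}}')$config
  expect_equal(cfg2$wtp, 30000)
  expect_error(load_parameters('{"config": {"bogus": 1}}'), "unknown")
})
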
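p0 <- default_parameters()
specs0 <- parameter_specs()

test_that("distribution assignments honour their declared conventions", {
  asg <- build_assignments(specs0)

  # gamma: mean = base, sd = range width / 3.92, by construction
  g <- asg$cost_hosp_day
  expect_equal(g$shape / g$rate, 654)
  expect_equal(sqrt(g$shape) / g$rate, (785 - 523) / 3.92)

  # lognormal risk ratio: median at base, 95% CI width on the log scale
  ln <- asg$rr_hosp_tm
  expect_equal(exp(ln$meanlog), 0.5)
  expect_equal(ln$sdlog, (log(0.64) - log(0.36)) / 3.92)

  # beta: mean at base, central 95% interval matching the range width
  b <- asg$p_death_mdc
  expect_equal(b$shape1 / (b$shape1 + b$shape2), 0.0279)
  expect_equal(stats::qbeta(0.975, b$shape1, b$shape2) -
                 stats::qbeta(0.025, b$shape1, b$shape2),
               0.0383 - 0.0076, tolerance = 1e-6)

  # dirichlet: concentration scaled to the base simplex
  d <- asg$init_nyha
  expect_equal(d$alpha / sum(d$alpha), unname(d$base))
})

test_that("sampled values respect their supports and means", {
  set.seed(101)
  asg <- build_assignments(specs0)
  nd <- 20000
  u <- replicate(nd, sample_assignment(asg[["utility.I"]]))
  expect_true(all(u >= 0.78 & u <= 0.85))
  expect_equal(mean(u), (0.78 + 0.85) / 2, tolerance = 3 * 0.02 / sqrt(nd))

  g <- replicate(nd, sample_assignment(asg[["cost_hosp_day"]]))
  sd_g <- (785 - 523) / 3.92
  expect_equal(mean(g), 654, tolerance = 3 * sd_g / sqrt(nd))

  tri <- replicate(nd, sample_assignment(asg[["adherence"]]))
  expect_true(all(tri >= 0.64 & tri <= 0.96))
  expect_equal(mean(tri), (0.64 + 0.80 + 0.96) / 3,
               tolerance = 3 * 0.07 / sqrt(nd))

  dir <- replicate(nd, sample_assignment(asg[["transition.I"]]))
  expect_true(all(abs(colSums(dir) - 1) < 1e-12))
  expect_equal(rowMeans(dir), unname(p0$transition[1, ]),
               tolerance = 0.005)
  # the structural zero stays zero under Dirichlet sampling
  expect_true(all(dir[4, ] == 0))

  # zero-width range degenerates to a point mass
  sp <- specs0[specs0$name == "tm_monthly_cost", ]
  sp$low <- sp$high <- sp$base
  asg2 <- build_assignments(sp)
  expect_equal(replicate(50, sample_assignment(asg2$tm_monthly_cost)),
               rep(50, 50))
})

test_that("sampled parameter sets are valid and seeds reproduce draws", {
  asg <- build_assignments(specs0)
  set.seed(5)
  for (i in 1:25) {
    d <- sample_parameter_set(p0, asg)
    expect_identical(validate_parameters(d$params), character(0))
  }
  cfg <- fast_config()
  psa1 <- run_psa(p0, cfg, n = 30, seed = 9)
  psa2 <- run_psa(p0, cfg, n = 30, seed = 9)
  expect_identical(psa1$draws, psa2$draws)
  psa3 <- run_psa(p0, cfg, n = 30, seed = 10)
  expect_false(identical(psa1$draws$delta_cost, psa3$draws$delta_cost))
})

test_that("degenerate distributions reproduce the base case exactly", {
  sp <- specs0
  sp$low <- sp$high <- sp$base
  cfg <- fast_config()
  psa <- run_psa(p0, cfg, n = 5, seed = 3, specs = sp)
  base <- compare_strategies(run_cohort(p0, "CUC", cfg),
                             run_cohort(p0, "TM", cfg))
  expect_equal(psa$draws$delta_cost, rep(base$delta_cost, 5),
               tolerance = 1e-12)
  expect_equal(psa$draws$delta_qaly, rep(base$delta_qaly, 5),
               tolerance = 1e-12)
  expect_equal(psa$clamp_rate, 0)
})

test_that("acceptability curve complements sum to one and tie to quadrants", {
  cfg <- fast_config()
  psa <- run_psa(p0, cfg, n = 400, seed = 21)
  expect_equal(sum(psa$quadrant_fractions), 1)
  curve <- ceac(psa, wtp_grid = seq(0, 100000, by = 2500))
  expect_equal(curve$p_telemonitoring + curve$p_cuc,
               rep(1, nrow(curve)))
  # at zero WTP only cost-saving draws count for telemonitoring
  expect_equal(curve$p_telemonitoring[curve$wtp == 0],
               mean(psa$draws$delta_cost < 0))
})

test_that("Monte Carlo error shrinks like one over root n", {
  cfg <- fast_config()
  hw <- sapply(c(400, 800), function(n) {
    psa <- run_psa(p0, cfg, n = n, seed = 77)
    s <- psa$summary
    (s["delta_qaly", "ci_high"] - s["delta_qaly", "ci_low"]) / 2
  })
  ratio <- hw[2] / hw[1]
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 0.82)
})
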
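# Shared fixtures and independent oracles for the test suite.

# Short-horizon configuration used where the property under test does not
# depend on the full 10-year horizon.
fast_config <- function(horizon_years = 2, ...) {
  analysis_config(horizon_years = horizon_years, ...)
}

# A minimal run object for CEA arithmetic tests, bypassing the engine.
make_run <- function(total_cost, total_qaly, strategy = "CUC",
                     config = analysis_config()) {
  structure(list(strategy = strategy, total_cost = total_cost,
                 total_qaly = total_qaly, config = config),
            class = "hf_run")
}

# Brute-force one-cycle oracle: exhaustive enumeration over the death /
# survival-transition branches, written independently of cycle_transition.
naive_cycle_enum <- function(occupancy, transition, p_death) {
  out <- numeric(5)
  out[5] <- occupancy[5]
  for (i in 1:4) {
    m <- occupancy[i]
    out[5] <- out[5] + m * p_death          # death branch
    for (j in 1:4)                          # survival branch, then move
      out[j] <- out[j] + m * (1 - p_death) * transition[i, j]
  }
  out
}

expect_within_rel <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol * abs(expected),
              label = sprintf("%.6g within %.0f%% of %.6g", actual,
                              100 * tol, expected))
}
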
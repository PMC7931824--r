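# Brute-force validation tools: an individual-level microsimulation with
# the identical dynamics to the cohort engine, and a generator of random
# structurally valid parameter sets for property-based testing.

#' Individual-level microsimulation of one strategy arm
#'
#' Samples `n_patients` trajectories under exactly the dynamics of the
#' cohort engine: each patient draws avoidance and adherence attributes at
#' entry and an initial NYHA class from the initial distribution; each
#' cycle, hospitalization and death events are drawn with the
#' probabilities of [effective_event_probabilities()], survivors move
#' among NYHA classes by the monthly transition matrix, and realized costs
#' and QALYs accrue exactly as in [accrue_cycle()] (including the terminal
#' admission on death and the telemonitoring fees). The sample mean is an
#' unbiased estimator of the cohort-model totals under start-of-cycle
#' accrual; the half-cycle correction setting in `config` is therefore
#' ignored here, and equivalence checks against [run_cohort()] must use a
#' configuration with `half_cycle_correction = FALSE`.
#'
#' @param params An `hf_parameters` object.
#' @param strategy `"CUC"` or `"TM"`.
#' @param n_patients Number of simulated patients (>= 1).
#' @param config An `hf_config` object.
#' @param seed Integer seed; trajectories are reproducible for a fixed
#'   seed.
#' @return An object of class `hf_microsim`: list with `strategy`,
#'   `n_patients`, `mean_cost`, `se_cost`, `mean_qaly`, `se_qaly`,
#'   `mean_life_years`, and the per-patient totals in `patients`.
#' @examples
#' \donttest{
#' ms <- microsimulate(default_parameters(), "CUC", 2000,
#'                     analysis_config(half_cycle_correction = FALSE),
#'                     seed = 1)
#' c(ms$mean_cost, ms$mean_qaly)
#' }
#' @export
microsimulate <- function(params, strategy, n_patients,
                          config = analysis_config(half_cycle_correction
                                                   = FALSE),
                          seed = NULL) {
  check_strategy(strategy)
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be >= 1", call. = FALSE)
  n <- as.integer(n_patients)
  if (!is.null(seed)) set.seed(seed)
  n_cycles <- round(12 * config$horizon_years)
  win <- avoidance_cycles(params)
  hosp_cost <- params$cost_hosp_day * params$los_days

  avoider <- stats::runif(n) < params$avoidance
  adherent <- if (strategy == "TM") stats::runif(n) < params$adherence
              else rep(FALSE, n)
  state <- sample.int(4, n, replace = TRUE, prob = params$init_nyha)
  cost <- rep(if (strategy == "TM") params$tm_setup_cost else 0, n)
  qaly <- numeric(n)
  months_alive <- numeric(n)
  tm_fee <- strategy == "TM" & avoider

  # effective probabilities for the four (avoider, adherent) combinations,
  # inside and outside the avoidance window
  combo_idx <- 1L + avoider + 2L * adherent
  prob_tab <- function(in_window) {
    combos <- expand.grid(avoider = c(FALSE, TRUE),
                          adherent = c(FALSE, TRUE))
    tab <- matrix(NA_real_, 4, 2,
                  dimnames = list(NULL, c("p_hosp", "p_death")))
    for (k in which(tabulate(combo_idx, 4) > 0)) {
      p <- params
      if (!in_window) p$avoidance_duration_years <- 0
      tab[k, ] <- effective_event_probabilities(
        p, combos$avoider[k], combos$adherent[k], strategy, 0)
    }
    tab
  }
  tab_in <- prob_tab(TRUE)
  tab_out <- prob_tab(FALSE)

  for (t in seq_len(n_cycles) - 1L) {
    alive <- state < 5L
    if (!any(alive)) break
    tab <- if (t < win) tab_in else tab_out
    ph <- tab[combo_idx, "p_hosp"]
    pd <- tab[combo_idx, "p_death"]
    hosp <- alive & stats::runif(n) < ph
    death <- alive & stats::runif(n) < pd
    df <- discount_factor(t, config$discount_rate_annual)
    u <- params$utility[state]
    d <- params$disutility_hosp[state]
    q_c <- ifelse(alive, (u - hosp * d) / 12, 0)
    c_c <- ifelse(alive,
                  params$cost_outpatient_month +
                    (hosp + death) * hosp_cost +
                    ifelse(tm_fee, params$tm_monthly_cost, 0),
                  0)
    qaly <- qaly + df * q_c
    cost <- cost + df * c_c
    months_alive <- months_alive + alive
    surv <- alive & !death
    new_state <- state  # draw into a copy so no one transitions twice
    for (cl in 1:4) {
      idx <- which(surv & state == cl)
      if (length(idx) > 0)
        new_state[idx] <- sample.int(4, length(idx), replace = TRUE,
                                     prob = params$transition[cl, ])
    }
    state <- new_state
    state[death] <- 5L
  }
  se <- function(x) stats::sd(x) / sqrt(n)
  structure(list(strategy = strategy, n_patients = n,
                 mean_cost = mean(cost), se_cost = se(cost),
                 mean_qaly = mean(qaly), se_qaly = se(qaly),
                 mean_life_years = mean(months_alive) / 12,
                 patients = data.frame(cost = cost, qaly = qaly,
                                       months_alive = months_alive,
                                       avoider = avoider,
                                       adherent = adherent)),
            class = "hf_microsim")
}

#' @export
print.hf_microsim <- function(x, ...) {
  cat(sprintf("<hf_microsim> %s arm, %d patients\n", x$strategy,
              x$n_patients))
  cat(sprintf("  mean cost  %10.2f (SE %.2f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  mean QALYs %10.4f (SE %.4f)\n", x$mean_qaly, x$se_qaly))
  invisible(x)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Random structurally valid parameter set
#'
#' Generates a parameter set with the model's structural constraints for
#' property-based testing: Dirichlet-sampled initial distribution and
#' row-stochastic transition matrix (diagonally concentrated, as chronic
#' disease progression matrices are), event probabilities uniform in
#' (0, 0.2), risk ratios uniform in (0.3, 1.2), utilities decreasing in
#' NYHA class, bounded disutilities, and non-negative costs. The result
#' always passes [validate_parameters()].
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An `hf_parameters` object.
#' @export
random_parameter_set <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- default_parameters()
  p$init_nyha[] <- rdirichlet1(stats::runif(4, 0.5, 4))
  for (i in 1:4) {
    alpha <- stats::runif(4, 0.2, 2)
    alpha[i] <- stats::runif(1, 5, 30)   # diagonal dominance
    p$transition[i, ] <- rdirichlet1(alpha)
  }
  p$p_hosp_mdc <- stats::runif(1, 0, 0.2)
  p$p_death_mdc <- stats::runif(1, 0, 0.2)
  p$rr_hosp_mdc <- stats::runif(1, 0.3, 1.2)
  p$rr_death_mdc <- stats::runif(1, 0.3, 1.2)
  p$rr_hosp_tm <- stats::runif(1, 0.3, 1.2)
  p$rr_death_tm <- stats::runif(1, 0.3, 1.2)
  p$adherence <- stats::runif(1)
  p$avoidance <- stats::runif(1)
  p$avoidance_duration_years <- stats::runif(1, 0.5, 2)
  p$utility[] <- sort(stats::runif(4, 0.3, 0.95), decreasing = TRUE)
  p$disutility_hosp[] <- stats::runif(4, 0, 0.25)
  p$cost_hosp_day <- stats::runif(1, 100, 1000)
  p$los_days <- stats::runif(1, 3, 12)
  p$cost_outpatient_month <- stats::runif(1, 50, 400)
  p$tm_setup_cost <- stats::runif(1, 0, 200)
  p$tm_monthly_cost <- stats::runif(1, 0, 100)
  p
}
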
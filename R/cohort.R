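# Deterministic Markov cohort engine.
#
# Strategy arms: "CUC" (multidisciplinary care under COVID-19, a fraction of
# patients avoiding in-person care for a limited period) and "TM" (the same
# plus smartphone telemonitoring). Model structure, fixed by design:
#   - death is a competing event applied to every alive state before the
#     NYHA redistribution (the printed transition matrix is conditional on
#     survival);
#   - care avoiders face the without-multidisciplinary-care event risks
#     (base probability divided by the MDC risk ratio) while avoidance
#     lasts;
#   - telemonitoring risk ratios act on patients who both avoid in-person
#     care and adhere to telemonitoring -- the program substitutes remote
#     management for the forgone clinic care -- and persist over the full
#     horizon;
#   - every death incurs one terminal HF admission (daily cost x length of
#     stay) in addition to the expected admissions from the hospitalization
#     probability;
#   - the recurrent telemonitoring fee accrues for avoiders in the TM arm
#     (the patients the remote service manages); the one-time setup cost is
#     charged for the whole TM arm at entry, undiscounted.

STRATEGIES <- c("CUC", "TM")

check_strategy <- function(strategy) {
  if (!is.character(strategy) || length(strategy) != 1 ||
        !(strategy %in% STRATEGIES))
    stop("strategy must be one of: ", paste(STRATEGIES, collapse = ", "),
         call. = FALSE)
  strategy
}

#' Avoidance/adherence strata of a strategy arm
#'
#' Care avoidance and telemonitoring adherence are time-fixed patient
#' attributes assigned at model entry and treated as independent. The CUC
#' arm splits into avoider/non-avoider strata; the telemonitoring arm into
#' the four-way cross of avoidance and adherence.
#'
#' @param params An `hf_parameters` object.
#' @param strategy `"CUC"` or `"TM"`.
#' @return A data.frame with columns `avoider`, `adherent` (logical;
#'   `adherent` is `NA` under CUC) and `weight` (sums to 1).
#' @examples
#' build_strata(default_parameters(), "CUC")$weight  # 0.261, 0.739
#' @export
build_strata <- function(params, strategy) {
  check_strategy(strategy)
  av <- params$avoidance
  if (strategy == "CUC") {
    out <- data.frame(avoider = c(TRUE, FALSE), adherent = NA,
                      weight = c(av, 1 - av))
  } else {
    ad <- params$adherence
    out <- expand.grid(adherent = c(TRUE, FALSE), avoider = c(TRUE, FALSE))
    out <- out[, c("avoider", "adherent")]
    out$weight <- ifelse(out$avoider, av, 1 - av) *
      ifelse(out$adherent, ad, 1 - ad)
  }
  rownames(out) <- NULL
  out
}

avoidance_cycles <- function(params) {
  ceiling(params$avoidance_duration_years * 12)
}

#' Effective monthly event probabilities for one stratum
#'
#' Starts from the multidisciplinary-care hospitalization and mortality
#' probabilities. Avoiders, while avoidance lasts, face the
#' without-multidisciplinary-care risks (base divided by the MDC risk
#' ratio). In the telemonitoring arm, patients who avoid in-person care and
#' adhere to telemonitoring have both probabilities multiplied by the
#' telemonitoring risk ratios. Results are clamped to \[0, 1\] with a
#' warning if a division exceeds one.
#'
#' @param params An `hf_parameters` object.
#' @param avoider,adherent Logical stratum attributes (`adherent` ignored
#'   under CUC).
#' @param strategy `"CUC"` or `"TM"`.
#' @param cycle_index 0-based cycle number.
#' @return Named numeric vector `c(p_hosp =, p_death =)`.
#' @examples
#' p <- default_parameters()
#' effective_event_probabilities(p, FALSE, FALSE, "CUC", 0)
#' effective_event_probabilities(p, TRUE, FALSE, "CUC", 0)   # /RR_mdc
#' effective_event_probabilities(p, TRUE, TRUE, "TM", 24)    # x RR_tm only
#' @export
effective_event_probabilities <- function(params, avoider, adherent,
                                          strategy, cycle_index) {
  check_strategy(strategy)
  stopifnot(cycle_index >= 0)
  ph <- params$p_hosp_mdc
  pd <- params$p_death_mdc
  if (isTRUE(avoider) && cycle_index < avoidance_cycles(params)) {
    ph <- ph / params$rr_hosp_mdc
    pd <- pd / params$rr_death_mdc
  }
  if (strategy == "TM" && isTRUE(avoider) && isTRUE(adherent)) {
    ph <- ph * params$rr_hosp_tm
    pd <- pd * params$rr_death_tm
  }
  if (ph > 1 || pd > 1)
    warning(sprintf(
      "effective probability exceeds 1 (p_hosp=%.4g, p_death=%.4g); clamped",
      ph, pd), call. = FALSE)
  c(p_hosp = min(max(ph, 0), 1), p_death = min(max(pd, 0), 1))
}

#' One Markov cycle: competing death, then NYHA redistribution
#'
#' Applies monthly all-cause mortality uniformly to all alive states, moves
#' that mass to `Dead`, and redistributes survivors among NYHA I-IV by the
#' monthly transition matrix. Total mass is conserved to machine precision.
#'
#' @param occupancy Length-5 non-negative vector over (NYHA I-IV, Dead).
#' @param transition 4x4 row-stochastic monthly matrix among NYHA classes.
#' @param p_death Monthly all-cause mortality probability.
#' @return The next cycle's length-5 occupancy vector.
#' @export
cycle_transition <- function(occupancy, transition, p_death) {
  stopifnot(length(occupancy) == 5, all(occupancy >= 0),
            p_death >= 0, p_death <= 1)
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition matrix is not row-stochastic", call. = FALSE)
  alive <- occupancy[1:4]
  new_dead <- sum(alive) * p_death
  alive2 <- as.vector((alive * (1 - p_death)) %*% transition)
  stats::setNames(c(alive2, occupancy[5] + new_dead), STATES)
}

discount_factor <- function(cycle_index, rate) {
  (1 + rate)^(-cycle_index / 12)
}

#' Cost and QALY accrual for one cycle
#'
#' With accrual-basis occupancy `o(c)` over NYHA classes and alive mass `a`:
#' the cycle's QALYs are `sum_c o(c) * (u(c) - p_hosp * d(c)) / 12`
#' (hospitalization disutility as an expected within-cycle decrement on the
#' annual utility weight); the cycle's costs are outpatient care for all
#' alive patients, expected admissions `a * (p_hosp + p_death)` at daily
#' cost times length of stay (events plus one terminal admission per
#' death), and the recurrent telemonitoring fee when `tm_fee` is on. Both
#' are discounted by `(1 + r)^(-cycle_index / 12)`.
#'
#' @param occupancy Length-5 occupancy vector used as the accrual basis
#'   (already start-of-cycle, end-of-cycle, or the half-cycle average).
#' @param params An `hf_parameters` object.
#' @param strategy `"CUC"` or `"TM"`.
#' @param p_hosp,p_death Effective monthly event probabilities.
#' @param cycle_index 0-based cycle number (drives discounting).
#' @param config An `hf_config` object.
#' @param tm_fee Does the recurrent telemonitoring fee accrue for this
#'   stratum this cycle?
#' @return A list with `discounted_cost`, `discounted_qaly`,
#'   `expected_hospitalizations` (undiscounted event mass) and `alive_mass`.
#' @export
accrue_cycle <- function(occupancy, params, strategy, p_hosp, p_death,
                         cycle_index, config, tm_fee = FALSE) {
  check_strategy(strategy)
  alive <- occupancy[1:4]
  a <- sum(alive)
  eff_u <- params$utility - p_hosp * params$disutility_hosp
  if (any(eff_u < -1e-12))
    stop("negative effective utility; invalid utility/disutility inputs",
         call. = FALSE)
  qaly <- sum(alive * eff_u) / 12
  hosp_cost <- params$cost_hosp_day * params$los_days
  cost <- a * params$cost_outpatient_month +
    a * (p_hosp + p_death) * hosp_cost
  if (strategy == "TM" && tm_fee) cost <- cost + a * params$tm_monthly_cost
  df <- discount_factor(cycle_index, config$discount_rate_annual)
  list(discounted_cost = df * cost,
       discounted_qaly = df * qaly,
       expected_hospitalizations = a * p_hosp,
       alive_mass = a)
}

#' Run one strategy arm of the cohort model
#'
#' Initializes each stratum at `weight * init_nyha`, iterates
#' `round(12 * horizon_years)` monthly cycles of accrue-then-transition,
#' and returns the per-cycle trace with discounted totals. The
#' telemonitoring arm adds the one-time setup cost, undiscounted, at entry.
#' The accrual basis per cycle follows `config`: start- or end-of-cycle
#' occupancy, or their average under the half-cycle correction (default).
#'
#' @param params An `hf_parameters` object; must pass
#'   [validate_parameters()].
#' @param strategy `"CUC"` or `"TM"`.
#' @param config An `hf_config` object.
#' @return An object of class `hf_run`: list with `strategy`, `trace` (a
#'   data.frame with one row per cycle: `cycle`, `discounted_cost`,
#'   `discounted_qaly`, `expected_hospitalizations`, `alive_mass`, and
#'   occupancy by state), `total_cost`, `total_qaly` (discounted),
#'   `life_years` (undiscounted expected years alive on the same accrual
#'   basis), and `one_time_cost`.
#' @examples
#' run <- run_cohort(default_parameters(), "CUC", analysis_config())
#' c(run$total_cost, run$total_qaly)
#' @export
run_cohort <- function(params, strategy, config = analysis_config()) {
  check_strategy(strategy)
  viol <- validate_parameters(params)
  if (length(viol) > 0)
    stop("invalid parameters:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  n_cycles <- round(12 * config$horizon_years)
  strata <- build_strata(params, strategy)
  one_time <- if (strategy == "TM") params$tm_setup_cost else 0
  win <- avoidance_cycles(params)
  P <- params$transition
  hosp_unit <- params$cost_hosp_day * params$los_days
  outp <- params$cost_outpatient_month
  disc <- discount_factor(seq_len(max(n_cycles, 0)) - 1L,
                          config$discount_rate_annual)
  hcc <- config$half_cycle_correction
  start_acc <- config$accrual_timing == "start_of_cycle"

  cost <- qaly <- hosp <- alive <- numeric(max(n_cycles, 0))
  occ_by_state <- matrix(0, nrow = max(n_cycles, 0), ncol = 5,
                         dimnames = list(NULL, STATES))
  life_years <- 0
  for (s in seq_len(nrow(strata))) {
    avoider <- strata$avoider[s]
    adherent <- isTRUE(strata$adherent[s])
    # probabilities only change when the avoidance window closes
    pr_in <- effective_event_probabilities(params, avoider, adherent,
                                           strategy, 0)
    pr_out <- effective_event_probabilities(params, avoider, adherent,
                                            strategy, win)
    if (any(params$utility -
              max(pr_in[[1L]], pr_out[[1L]]) * params$disutility_hosp <
              -1e-12))
      stop("negative effective utility; invalid utility/disutility inputs",
           call. = FALSE)
    occ <- strata$weight[s] * params$init_nyha
    dead <- 0
    tm_fee <- strategy == "TM" && avoider
    fee <- if (tm_fee) params$tm_monthly_cost else 0
    for (t in seq_len(n_cycles) - 1L) {
      pr <- if (t < win) pr_in else pr_out
      ph <- pr[[1L]]; pd <- pr[[2L]]
      occ_end <- as.vector((occ * (1 - pd)) %*% P)
      basis <- if (hcc) (occ + occ_end) / 2
               else if (start_acc) occ else occ_end
      a <- sum(basis)
      i <- t + 1L
      df <- disc[i]
      cost[i] <- cost[i] + df *
        (a * (outp + (ph + pd) * hosp_unit + fee))
      qaly[i] <- qaly[i] +
        df * sum(basis * (params$utility - ph * params$disutility_hosp)) / 12
      hosp[i] <- hosp[i] + a * ph
      alive[i] <- alive[i] + a
      dead_basis <- if (hcc) dead + sum(occ) * pd / 2
                    else if (start_acc) dead else dead + sum(occ) * pd
      occ_by_state[i, ] <- occ_by_state[i, ] + c(basis, dead_basis)
      life_years <- life_years + a / 12
      dead <- dead + sum(occ) * pd
      occ <- occ_end
    }
  }
  trace <- data.frame(cycle = seq_len(n_cycles) - 1L,
                      discounted_cost = cost, discounted_qaly = qaly,
                      expected_hospitalizations = hosp, alive_mass = alive)
  trace <- cbind(trace, as.data.frame(occ_by_state))
  structure(list(strategy = strategy, trace = trace,
                 total_cost = sum(cost) + one_time,
                 total_qaly = sum(qaly),
                 life_years = life_years,
                 one_time_cost = one_time,
                 config = config),
            class = "hf_run")
}

#' @export
print.hf_run <- function(x, ...) {
  cat(sprintf("<hf_run> %s arm: %d cycles\n", x$strategy, nrow(x$trace)))
  cat(sprintf("  discounted cost  %10.2f US$\n", x$total_cost))
  cat(sprintf("  discounted QALYs %10.4f\n", x$total_qaly))
  cat(sprintf("  life-years       %10.4f (undiscounted)\n", x$life_years))
  invisible(x)
}

#' Export a per-cycle trace as CSV
#'
#' @param run An `hf_run` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(run, path) {
  tr <- run$trace
  tr$strategy <- run$strategy
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
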
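#' @keywords internal
"_PACKAGE"

NYHA <- c("I", "II", "III", "IV")
STATES <- c(NYHA, "Dead")

#' Base-case model parameters
#'
#' Returns the full parameterization of the heart-failure telemonitoring
#' decision model: initial NYHA class distribution, monthly NYHA transition
#' matrix, monthly event probabilities under multidisciplinary care, risk
#' ratios for care with versus without multidisciplinary management and with
#' versus without telemonitoring, adherence and COVID-19-related care
#' avoidance fractions, NYHA utilities and hospitalization disutilities, and
#' unit costs (US $, 2020).
#'
#' All values are the model's published base case. Use
#' [parameter_specs()] for the associated sensitivity ranges and
#' probabilistic distribution families, and [load_parameters()] to override
#' individual fields from a JSON configuration.
#'
#' @return An object of class `hf_parameters`: a named list with fields
#'   `init_nyha` (length-4 proportions), `transition` (4x4 row-stochastic
#'   monthly matrix), `p_hosp_mdc`, `p_death_mdc` (monthly event
#'   probabilities), `rr_hosp_mdc`, `rr_death_mdc`, `rr_hosp_tm`,
#'   `rr_death_tm` (risk ratios), `adherence`, `avoidance`,
#'   `avoidance_duration_years`, `utility`, `disutility_hosp` (length-4,
#'   per NYHA class), `cost_hosp_day`, `los_days`, `cost_outpatient_month`,
#'   `tm_setup_cost`, `tm_monthly_cost`.
#' @examples
#' p <- default_parameters()
#' p$p_hosp_mdc
#' rowSums(p$transition)
#' @export
default_parameters <- function() {
  transition <- rbind(
    c(0.9597, 0.0394, 0.0009, 0),
    c(0.0073, 0.9877, 0.0039, 0.0011),
    c(0.0010, 0.0443, 0.8843, 0.0704),
    c(0.0010, 0.0443, 0.8515, 0.1032))
  dimnames(transition) <- list(NYHA, NYHA)
  p <- list(
    init_nyha = stats::setNames(c(0.09, 0.44, 0.34, 0.13), NYHA),
    transition = transition,
    p_hosp_mdc = 0.0296,
    p_death_mdc = 0.0279,
    rr_hosp_mdc = 0.74,
    rr_death_mdc = 0.75,
    rr_hosp_tm = 0.50,
    rr_death_tm = 0.81,
    adherence = 0.80,
    avoidance = 0.261,
    avoidance_duration_years = 1.5,
    utility = stats::setNames(c(0.82, 0.74, 0.64, 0.46), NYHA),
    disutility_hosp = stats::setNames(c(0.04, 0.07, 0.10, 0.29), NYHA),
    cost_hosp_day = 654,
    los_days = 8,
    cost_outpatient_month = 197,
    tm_setup_cost = 80,
    tm_monthly_cost = 50)
  structure(p, class = "hf_parameters")
}

#' Parameter specifications: ranges and distribution families
#'
#' One row per elementary model input, giving its base-case value, the range
#' used in deterministic sensitivity analysis, the distribution family used
#' in probabilistic sensitivity analysis, units, and a parameter group.
#' Vector-valued inputs (initial NYHA distribution, transition-matrix rows,
#' utilities, disutilities) appear as one row per component; components of a
#' Dirichlet-distributed simplex share the `dirichlet_row` family and a
#' common `dirichlet_group`.
#'
#' The NYHA-IV transition row is published with ranges duplicated from the
#' NYHA-III row; since its base values are internally consistent (they sum
#' to one) they are kept, and ranges for that row are regenerated as +/-20%
#' of the row-IV base values (the model's default range rule for inputs
#' without a usable published range).
#'
#' @param params An `hf_parameters` object whose base values populate the
#'   `base` column; defaults to [default_parameters()].
#' @param range_fraction Half-width, as a fraction of base, for ranges that
#'   must be regenerated (default 0.20).
#' @return A data.frame with columns `name`, `base`, `low`, `high`,
#'   `family`, `units`, `group`, `dirichlet_group`.
#' @export
parameter_specs <- function(params = default_parameters(),
                            range_fraction = 0.20) {
  row <- function(name, base, low, high, family, units, group,
                  dgroup = NA_character_) {
    data.frame(name = name, base = base, low = low, high = high,
               family = family, units = units, group = group,
               dirichlet_group = dgroup, stringsAsFactors = FALSE)
  }
  sp <- list()
  init_rng <- rbind(c(0.081, 0.099), c(0.396, 0.484),
                    c(0.306, 0.374), c(0.086, 0.174))
  for (i in 1:4) {
    sp[[length(sp) + 1]] <- row(paste0("init_nyha.", NYHA[i]),
                                params$init_nyha[i],
                                init_rng[i, 1], init_rng[i, 2],
                                "dirichlet_row", "proportion", "clinical",
                                "init_nyha")
  }
  trans_rng <- list(
    I   = rbind(c(0.9538, 0.9678), c(0.0315, 0.0473),
                c(0.0007, 0.0011), c(0, 0.0011)),
    II  = rbind(c(0.0058, 0.0088), c(0.9852, 0.9902),
                c(0.0031, 0.0047), c(0.0009, 0.0013)),
    III = rbind(c(0.0008, 0.0012), c(0.0354, 0.0532),
                c(0.8612, 0.9074), c(0.0563, 0.0845)),
    IV  = NULL)  # regenerated below: published ranges duplicate row III
  for (i in 1:4) {
    rng <- trans_rng[[i]]
    for (j in 1:4) {
      b <- params$transition[i, j]
      lh <- if (is.null(rng)) {
        c(max(b * (1 - range_fraction), 0),
          min(b * (1 + range_fraction), 1))
      } else rng[j, ]
      sp[[length(sp) + 1]] <- row(
        paste0("transition.", NYHA[i], ".", NYHA[j]), b, lh[1], lh[2],
        "dirichlet_row", "probability/month", "clinical",
        paste0("transition.", NYHA[i]))
    }
  }
  scal <- function(name, low, high, family, units, group)
    row(name, params[[name]], low, high, family, units, group)
  sp <- c(sp, list(
    scal("p_hosp_mdc", 0.0237, 0.15, "beta", "probability/month", "clinical"),
    scal("p_death_mdc", 0.0076, 0.0383, "beta", "probability/month",
         "clinical"),
    scal("rr_hosp_mdc", 0.64, 0.87, "lognormal_rr", "risk ratio", "clinical"),
    scal("rr_death_mdc", 0.59, 0.96, "lognormal_rr", "risk ratio",
         "clinical"),
    scal("rr_hosp_tm", 0.36, 0.64, "lognormal_rr", "risk ratio", "clinical"),
    scal("rr_death_tm", 0.70, 0.94, "lognormal_rr", "risk ratio", "clinical"),
    scal("adherence", 0.64, 0.96, "triangular", "proportion", "clinical"),
    scal("avoidance", 0.21, 0.315, "triangular", "proportion", "clinical"),
    scal("avoidance_duration_years", 0.5, 2, "triangular", "years",
         "clinical")))
  util_rng <- rbind(c(0.78, 0.85), c(0.69, 0.75), c(0.55, 0.77),
                    c(0.41, 0.61))
  disu_rng <- rbind(c(0.03, 0.05), c(0.06, 0.08), c(0.08, 0.12),
                    c(0.23, 0.35))
  for (i in 1:4) {
    sp[[length(sp) + 1]] <- row(paste0("utility.", NYHA[i]),
                                params$utility[i], util_rng[i, 1],
                                util_rng[i, 2], "uniform", "utility/year",
                                "utility")
    sp[[length(sp) + 1]] <- row(paste0("disutility_hosp.", NYHA[i]),
                                params$disutility_hosp[i], disu_rng[i, 1],
                                disu_rng[i, 2], "uniform", "utility/year",
                                "utility")
  }
  sp <- c(sp, list(
    scal("cost_hosp_day", 523, 785, "gamma", "US$/day", "cost"),
    scal("los_days", 6, 10, "triangular", "days", "cost"),
    scal("cost_outpatient_month", 158, 236, "gamma", "US$/month", "cost"),
    scal("tm_setup_cost", 64, 96, "gamma", "US$", "cost"),
    scal("tm_monthly_cost", 40, 60, "gamma", "US$/month", "cost")))
  out <- do.call(rbind, sp)
  rownames(out) <- NULL
  bad <- out$low > out$base | out$base > out$high
  if (any(bad)) stop("spec range excludes base for: ",
                     paste(out$name[bad], collapse = ", "))
  out
}

#' Validate a parameter set
#'
#' Checks every structural invariant the cohort engine relies on:
#' `init_nyha` and each transition row sum to one (tolerance 1e-9), all
#' probabilities and proportions lie in \[0, 1\], utilities in \[0, 1\],
#' disutilities and costs non-negative, risk ratios positive, avoidance
#' duration positive.
#'
#' @param params An `hf_parameters` object (or plain list with the same
#'   fields).
#' @return A character vector of violation messages, empty when the set is
#'   valid. Violations are returned as data, not raised as errors.
#' @examples
#' validate_parameters(default_parameters())  # character(0)
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  p <- params
  if (abs(sum(p$init_nyha) - 1) > 1e-9)
    say("init_nyha sums to %.10f, must sum to 1", sum(p$init_nyha))
  if (any(p$init_nyha < 0 | p$init_nyha > 1))
    say("init_nyha has entries outside [0,1]")
  if (!is.matrix(p$transition) || !all(dim(p$transition) == c(4, 4))) {
    say("transition must be a 4x4 matrix")
  } else {
    rs <- rowSums(p$transition)
    for (i in which(abs(rs - 1) > 1e-9))
      say("transition row %s sums to %.10f, must sum to 1", NYHA[i], rs[i])
    if (any(p$transition < 0 | p$transition > 1))
      say("transition has entries outside [0,1]")
  }
  for (f in c("p_hosp_mdc", "p_death_mdc", "adherence", "avoidance")) {
    x <- p[[f]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      say("%s = %s violates bounds [0,1]", f, format(p[[f]]))
  }
  for (f in c("rr_hosp_mdc", "rr_death_mdc", "rr_hosp_tm", "rr_death_tm"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
          p[[f]] <= 0)
      say("%s = %s must be a positive risk ratio", f, format(p[[f]]))
  if (any(p$utility < 0 | p$utility > 1))
    say("utility = (%s) violates bounds [0,1]",
        paste(format(p$utility), collapse = ", "))
  if (any(p$disutility_hosp < 0))
    say("disutility_hosp = (%s) must be non-negative",
        paste(format(p$disutility_hosp), collapse = ", "))
  for (f in c("cost_hosp_day", "los_days", "cost_outpatient_month",
              "tm_setup_cost", "tm_monthly_cost"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
          p[[f]] < 0)
      say("%s = %s must be non-negative", f, format(p[[f]]))
  if (!is.numeric(p$avoidance_duration_years) ||
        p$avoidance_duration_years < 0)
    say("avoidance_duration_years = %s must be non-negative",
        format(p$avoidance_duration_years))
  v
}

#' Analysis settings
#'
#' Settings shared by every analysis: horizon, discounting, willingness to
#' pay, probabilistic iteration count, and the two cycle-accrual
#' conventions. Cycle length is fixed at one month.
#'
#' @param horizon_years Simulated horizon in years (default 10).
#' @param discount_rate_annual Annual discount rate applied to both costs
#'   and QALYs (default 0.03).
#' @param wtp Willingness-to-pay threshold in US $ per QALY (default 48937,
#'   one GDP per capita).
#' @param psa_iterations Monte Carlo iterations for the probabilistic
#'   sensitivity analysis (default 10000).
#' @param rng_seed Integer seed for reproducible sampling, or `NULL`.
#' @param dsa_default_range_fraction Half-width fraction for sensitivity
#'   ranges of inputs without a published range (default 0.20).
#' @param accrual_timing `"start_of_cycle"` (state occupancy at cycle start
#'   accrues the cycle, the default) or `"end_of_cycle"`.
#' @param half_cycle_correction Accrue on the average of start- and
#'   end-of-cycle occupancy, approximating mid-cycle transitions (default
#'   `TRUE`; overrides `accrual_timing` when on).
#' @return An object of class `hf_config`.
#' @export
analysis_config <- function(horizon_years = 10,
                            discount_rate_annual = 0.03,
                            wtp = 48937,
                            psa_iterations = 10000,
                            rng_seed = NULL,
                            dsa_default_range_fraction = 0.20,
                            accrual_timing = c("start_of_cycle",
                                               "end_of_cycle"),
                            half_cycle_correction = TRUE) {
  accrual_timing <- match.arg(accrual_timing)
  stopifnot(horizon_years >= 0, discount_rate_annual >= 0,
            psa_iterations >= 1, wtp >= 0)
  structure(list(horizon_years = horizon_years,
                 cycle_length_months = 1,
                 discount_rate_annual = discount_rate_annual,
                 wtp = wtp,
                 psa_iterations = as.integer(psa_iterations),
                 rng_seed = rng_seed,
                 dsa_default_range_fraction = dsa_default_range_fraction,
                 accrual_timing = accrual_timing,
                 half_cycle_correction = half_cycle_correction),
            class = "hf_config")
}

param_template <- function() {
  p <- unclass(default_parameters())
  lapply(p, function(x) x)
}

#' Load parameters and settings from a JSON configuration
#'
#' Reads a JSON document whose keys mirror the fields of
#' [default_parameters()] and [analysis_config()] (the latter under a
#' `"config"` key). Keys present override defaults; unknown keys are
#' rejected; the merged parameter set must pass [validate_parameters()].
#'
#' @param config_source Path to a JSON file, or a JSON string.
#' @return A list with elements `params` (`hf_parameters`) and `config`
#'   (`hf_config`).
#' @examples
#' pc <- load_parameters('{"tm_monthly_cost": 60}')
#' pc$params$tm_monthly_cost
#' @export
load_parameters <- function(config_source) {
  doc <- tryCatch(
    jsonlite::fromJSON(config_source, simplifyVector = TRUE),
    error = function(e) stop("configuration parse failure in ",
                             substr(paste(config_source, collapse = " "),
                                    1, 60),
                             ": ", conditionMessage(e), call. = FALSE))
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("configuration must be a JSON object",
                          call. = FALSE)
  params <- unclass(default_parameters())
  cfg_over <- doc[["config"]]
  doc[["config"]] <- NULL
  unknown <- setdiff(names(doc), names(params))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(doc)) {
    val <- doc[[k]]
    if (k == "transition") {
      val <- as.matrix(val)
      dimnames(val) <- dimnames(params$transition)
    } else if (length(params[[k]]) == 4) {
      val <- stats::setNames(as.numeric(val), NYHA)
    }
    params[[k]] <- val
  }
  params <- structure(params, class = "hf_parameters")
  viol <- validate_parameters(params)
  if (length(viol) > 0)
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  cfg_defaults <- formals(analysis_config)
  if (is.null(cfg_over)) cfg_over <- list()
  unknown <- setdiff(names(cfg_over),
                     setdiff(names(cfg_defaults), ""))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config <- do.call(analysis_config, cfg_over)
  list(params = params, config = config)
}

#' Serialize a parameter set to JSON
#'
#' Produces a JSON document that [load_parameters()] reads back
#' field-for-field, for provenance records and round-trip storage.
#'
#' @param params An `hf_parameters` object.
#' @param path Optional file path; when given the JSON is also written
#'   there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
serialize_parameters <- function(params, path = NULL) {
  p <- unclass(params)
  p$transition <- unname(apply(p$transition, 1, function(r) r,
                               simplify = FALSE))
  p$transition <- lapply(p$transition, unname)
  for (k in c("init_nyha", "utility", "disutility_hosp"))
    p[[k]] <- unname(p[[k]])
  js <- jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write the parameter table as CSV
#'
#' @param path Output file path.
#' @param specs Parameter specification table from [parameter_specs()].
#' @return The path, invisibly.
#' @export
write_parameter_csv <- function(path, specs = parameter_specs()) {
  utils::write.csv(specs[, c("name", "base", "low", "high", "family",
                             "units", "group")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.hf_parameters <- function(x, ...) {
  cat("Heart-failure model parameters (monthly cycle)\n")
  cat(sprintf("  initial NYHA I-IV: %s\n",
              paste(format(x$init_nyha), collapse = " ")))
  cat(sprintf("  p(hosp) = %.4f  p(death) = %.4f per month (MDC)\n",
              x$p_hosp_mdc, x$p_death_mdc))
  cat(sprintf("  RR MDC hosp/death: %.2f / %.2f;  RR TM hosp/death: %.2f / %.2f\n",
              x$rr_hosp_mdc, x$rr_death_mdc, x$rr_hosp_tm, x$rr_death_tm))
  cat(sprintf("  adherence %.1f%%, avoidance %.1f%% for %.1f years\n",
              100 * x$adherence, 100 * x$avoidance,
              x$avoidance_duration_years))
  cat(sprintf("  costs: hosp %s$/day x %s days, outpatient %s$/mo, TM %s$ + %s$/mo\n",
              format(x$cost_hosp_day), format(x$los_days),
              format(x$cost_outpatient_month), format(x$tm_setup_cost),
              format(x$tm_monthly_cost)))
  invisible(x)
}

#' @export
print.hf_config <- function(x, ...) {
  cat(sprintf(
    "Analysis settings: %.3g-year horizon, %.1f%%/yr discount, WTP %s$/QALY\n",
    x$horizon_years, 100 * x$discount_rate_annual, format(x$wtp)))
  cat(sprintf("  accrual: %s%s; PSA iterations: %d\n", x$accrual_timing,
              if (x$half_cycle_correction) " with half-cycle correction"
              else "", x$psa_iterations))
  invisible(x)
}
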
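# Deterministic sensitivity analyses: one-way (tornado), threshold search,
# and the two-way telemonitoring risk-ratio grid.

#' Set one elementary parameter, by spec name
#'
#' Scalar names set the field directly. Vector components use dotted names
#' (`utility.III`, `init_nyha.II`, `transition.I.II`). Setting one
#' component of a simplex (initial distribution or a transition row)
#' rescales the remaining components proportionally over the remaining
#' mass, preserving row-stochasticity. Probabilities and proportions are
#' clamped to \[0, 1\] with a warning.
#'
#' @param params An `hf_parameters` object.
#' @param name Elementary parameter name as in [parameter_specs()].
#' @param value New value.
#' @return The modified `hf_parameters` object.
#' @export
set_parameter <- function(params, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  clamp01 <- function(x, what) {
    if (x < 0 || x > 1) {
      warning(sprintf("%s = %.4g clamped to [0,1]", what, x),
              call. = FALSE)
      x <- min(max(x, 0), 1)
    }
    x
  }
  renorm <- function(vec, j, v) {
    v <- clamp01(v, "simplex component")
    rest <- vec[-j]
    vec[j] <- v
    if (sum(rest) > 0) {
      vec[-j] <- rest * (1 - v) / sum(rest)
    } else {
      vec[-j] <- (1 - v) / length(rest)
    }
    vec
  }
  if (length(parts) == 1) {
    if (!name %in% names(params)) stop("unknown parameter: ", name,
                                       call. = FALSE)
    if (name %in% c("p_hosp_mdc", "p_death_mdc", "adherence", "avoidance"))
      value <- clamp01(value, name)
    params[[name]] <- value
  } else if (parts[1] == "transition") {
    i <- match(parts[2], NYHA); j <- match(parts[3], NYHA)
    if (is.na(i) || is.na(j)) stop("unknown parameter: ", name,
                                   call. = FALSE)
    params$transition[i, ] <- renorm(params$transition[i, ], j, value)
  } else if (parts[1] %in% c("init_nyha")) {
    j <- match(parts[2], NYHA)
    params$init_nyha <- renorm(params$init_nyha, j, value)
  } else if (parts[1] %in% c("utility", "disutility_hosp")) {
    j <- match(parts[2], NYHA)
    params[[parts[1]]][j] <- value
  } else stop("unknown parameter: ", name, call. = FALSE)
  params
}

run_pair <- function(params, config, wtp = config$wtp) {
  ref <- run_cohort(params, "CUC", config)
  alt <- run_cohort(params, "TM", config)
  compare_strategies(ref, alt, wtp = wtp)
}

# Signed cost-effectiveness metric for tornado ordering: the ICER where it
# is a meaningful ratio, carried as dc/dq otherwise (negative in the
# dominant quadrant), so dominant endpoints widen the spread instead of
# disappearing from it.
icer_metric <- function(cmp) {
  if (abs(cmp$delta_qaly) < QALY_TOL) return(NA_real_)
  cmp$delta_cost / cmp$delta_qaly
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs both strategy arms with each elementary parameter set to the low
#' and to the high end of its sensitivity range, all other inputs at base,
#' and records the resulting cost-effectiveness ratio at both ends. The
#' tornado metric is the signed incremental cost per QALY (negative when
#' the telemonitoring arm becomes dominant), `spread` is the absolute
#' width between the two endpoint values, and `relative_change` the larger
#' relative deviation from the base-case ICER. Parameters whose ICER moves
#' by more than `critical_fraction` are flagged critical.
#'
#' @param params An `hf_parameters` object.
#' @param config An `hf_config` object.
#' @param specs Parameter specification table ([parameter_specs()]); rows
#'   with `low == high` produce zero spread.
#' @param critical_fraction Relative-change threshold for the critical
#'   flag (default 0.20).
#' @return An object of class `hf_tornado`: a data.frame sorted by
#'   decreasing spread with columns `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `dominance_low`, `dominance_high`, `spread`,
#'   `relative_change`, `critical`, plus attributes `icer_base` and `wtp`.
#' @export
one_way_dsa <- function(params, config = analysis_config(),
                        specs = parameter_specs(params),
                        critical_fraction = 0.20) {
  base_cmp <- run_pair(params, config)
  icer_base <- icer_metric(base_cmp)
  n <- nrow(specs)
  out <- data.frame(parameter = specs$name, low = specs$low,
                    high = specs$high,
                    icer_low = NA_real_, icer_high = NA_real_,
                    dominance_low = NA_character_,
                    dominance_high = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (end in c("low", "high")) {
      p2 <- set_parameter(params, specs$name[i], specs[[end]][i])
      cmp <- run_pair(p2, config)
      out[[paste0("icer_", end)]][i] <- icer_metric(cmp)
      out[[paste0("dominance_", end)]][i] <- cmp$dominance
    }
  }
  out$spread <- abs(out$icer_high - out$icer_low)
  out$relative_change <- pmax(abs(out$icer_low - icer_base),
                              abs(out$icer_high - icer_base)) /
    abs(icer_base)
  out$critical <- out$relative_change > critical_fraction
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  structure(out, class = c("hf_tornado", "data.frame"),
            icer_base = icer_base, wtp = config$wtp)
}

#' @export
print.hf_tornado <- function(x, n = 10, ...) {
  cat(sprintf("<hf_tornado> base ICER %.0f US$/QALY; %d parameters, %d critical (>%.0f%%)\n",
              attr(x, "icer_base"), nrow(x), sum(x$critical), 20))
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}

#' Threshold search by bisection
#'
#' Finds the value of one parameter at which a cost-effectiveness criterion
#' changes sign, all other inputs at base: `dominance_onset` locates where
#' the telemonitoring arm's incremental cost crosses zero (onset of
#' dominance), `wtp_crossing` where its ICER crosses the willingness-to-pay
#' threshold. Endpoint signs are checked first; if the criterion does not
#' change sign over the bracket the search returns `NA` with a diagnostic
#' attribute.
#'
#' @param params An `hf_parameters` object.
#' @param parameter Elementary parameter name (see [set_parameter()]).
#' @param criterion `"dominance_onset"` or `"wtp_crossing"`.
#' @param bracket_low,bracket_high Search bracket.
#' @param config An `hf_config` object.
#' @param tol Relative bisection tolerance (default 1e-4).
#' @return The threshold value, or `NA` (attribute `"diagnostic"` says
#'   why).
#' @examples
#' \donttest{
#' threshold_search(default_parameters(), "p_hosp_mdc", "dominance_onset",
#'                  0.0296, 0.15)
#' }
#' @export
threshold_search <- function(params, parameter,
                             criterion = c("dominance_onset",
                                           "wtp_crossing"),
                             bracket_low, bracket_high,
                             config = analysis_config(), tol = 1e-4) {
  criterion <- match.arg(criterion)
  f <- function(x) {
    cmp <- run_pair(set_parameter(params, parameter, x), config)
    if (criterion == "dominance_onset") {
      cmp$delta_cost
    } else {
      m <- icer_metric(cmp)
      if (is.na(m)) sign(cmp$delta_cost) * config$wtp else m - config$wtp
    }
  }
  lo <- bracket_low; hi <- bracket_high
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) {
    out <- NA_real_
    attr(out, "diagnostic") <- sprintf(
      "criterion has the same sign at both endpoints (%.4g, %.4g); no crossing in [%g, %g]",
      flo, fhi, bracket_low, bracket_high)
    return(out)
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid; fhi <- fm
    }
    if ((hi - lo) <= tol * max(abs(mid), 1e-12)) break
  }
  (lo + hi) / 2
}

#' Two-way sensitivity grid over the telemonitoring risk ratios
#'
#' Re-runs both arms on a grid of (hospitalization, mortality) risk ratios
#' for telemonitoring, all other inputs at base, and labels each cell by
#' whether telemonitoring is the preferred option under the
#' willingness-to-pay rule.
#'
#' @param params An `hf_parameters` object.
#' @param config An `hf_config` object.
#' @param rr_hosp_range,rr_death_range Axis ranges (defaults 0.5-1 and
#'   0.81-1).
#' @param grid_n Grid points per axis (default 51).
#' @return An object of class `hf_twoway`: a data.frame with columns
#'   `rr_hosp_tm`, `rr_death_tm`, `accepted` (logical), `decision`,
#'   `icer`; attributes carry the axes.
#' @export
two_way_dsa <- function(params, config = analysis_config(),
                        rr_hosp_range = c(0.5, 1),
                        rr_death_range = c(0.81, 1),
                        grid_n = 51) {
  stopifnot(grid_n >= 2)
  ax1 <- seq(rr_hosp_range[1], rr_hosp_range[2], length.out = grid_n)
  ax2 <- seq(rr_death_range[1], rr_death_range[2], length.out = grid_n)
  grid <- expand.grid(rr_hosp_tm = ax1, rr_death_tm = ax2)
  grid$accepted <- NA
  grid$decision <- NA_character_
  grid$icer <- NA_real_
  for (k in seq_len(nrow(grid))) {
    p2 <- params
    p2$rr_hosp_tm <- grid$rr_hosp_tm[k]
    p2$rr_death_tm <- grid$rr_death_tm[k]
    cmp <- run_pair(p2, config)
    grid$accepted[k] <- cea_decision(cmp) == "alternative"
    grid$decision[k] <- cmp$dominance
    grid$icer[k] <- icer_metric(cmp)
  }
  structure(grid, class = c("hf_twoway", "data.frame"),
            axis_rr_hosp = ax1, axis_rr_death = ax2, wtp = config$wtp)
}

#' @export
print.hf_twoway <- function(x, ...) {
  cat(sprintf("<hf_twoway> %d x %d grid; telemonitoring accepted in %.1f%% of cells (WTP %s)\n",
              length(attr(x, "axis_rr_hosp")),
              length(attr(x, "axis_rr_death")),
              100 * mean(x$accepted), format(attr(x, "wtp"))))
  invisible(x)
}

#' Write tornado / two-way tables as CSV
#'
#' @param x An `hf_tornado` or `hf_twoway` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dsa_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
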
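# Probabilistic sensitivity analysis: distribution assignments derived
# from (base, low, high), Monte Carlo propagation through both arms, and
# the cost-effectiveness acceptability curve.

rtriangular <- function(n, low, mode, high) {
  if (high <= low) return(rep(mode, n))
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

# Concentration of a beta with mean m whose central 95% interval has the
# requested width; falls back to uniform(low, high) when no concentration
# can produce an interval that wide.
beta_concentration <- function(m, width) {
  w <- function(kappa)
    suppressWarnings(  # qbeta precision warnings at extreme skew
      stats::qbeta(0.975, kappa * m, kappa * (1 - m)) -
        stats::qbeta(0.025, kappa * m, kappa * (1 - m)))
  lo <- 1e-2; hi <- 1e8
  if (w(lo) < width) return(NA_real_)
  stats::uniroot(function(k) w(k) - width, c(lo, hi), tol = 1e-8)$root
}

#' Derive sampling distributions from the parameter table
#'
#' Maps each elementary parameter's `(base, low, high, family)` to a
#' concrete sampling distribution. Declared conventions: beta keeps the
#' mean at base with concentration solved numerically so the central 95%
#' interval has the width `high - low` (falling back to uniform when
#' infeasible); gamma matches mean = base and sd = `(high - low)/3.92`;
#' lognormal risk ratios take median = base and
#' `sdlog = (log high - log low)/3.92`; triangular uses
#' `(min, mode, max) = (low, base, high)`; Dirichlet rows use
#' concentration `alpha = kappa * base` with `kappa` chosen so the largest
#' component's sd matches its range width / 3.92. Zero-width ranges become
#' point masses.
#'
#' @param specs Parameter specification table from [parameter_specs()].
#' @return A named list of assignment records (class `hf_assignments`),
#'   one per scalar parameter and one per Dirichlet simplex.
#' @export
build_assignments <- function(specs = parameter_specs()) {
  out <- list()
  dgroups <- unique(stats::na.omit(specs$dirichlet_group))
  for (g in dgroups) {
    rows <- specs[!is.na(specs$dirichlet_group) & specs$dirichlet_group == g, ]
    p <- rows$base
    j <- which.max(p)
    sd_t <- (rows$high[j] - rows$low[j]) / 3.92
    kappa <- if (sd_t <= 0) Inf else p[j] * (1 - p[j]) / sd_t^2 - 1
    out[[g]] <- list(family = "dirichlet_row", names = rows$name,
                     base = p, alpha = if (is.finite(kappa)) kappa * p
                                       else NULL)
  }
  scalars <- specs[is.na(specs$dirichlet_group), ]
  for (i in seq_len(nrow(scalars))) {
    s <- scalars[i, ]
    rec <- list(family = s$family, base = s$base, low = s$low,
                high = s$high)
    if (s$high <= s$low) {
      rec$family <- "fixed"
    } else if (s$family == "beta") {
      kappa <- beta_concentration(s$base, s$high - s$low)
      if (is.na(kappa)) {
        warning(sprintf(
          "beta interval infeasible for %s; falling back to uniform",
          s$name), call. = FALSE)
        rec$family <- "uniform"
      } else {
        rec$shape1 <- kappa * s$base
        rec$shape2 <- kappa * (1 - s$base)
      }
    } else if (s$family == "gamma") {
      sd <- (s$high - s$low) / 3.92
      rec$shape <- (s$base / sd)^2
      rec$rate <- s$base / sd^2
    } else if (s$family == "lognormal_rr") {
      rec$meanlog <- log(s$base)
      rec$sdlog <- (log(s$high) - log(s$low)) / 3.92
    }
    out[[s$name]] <- rec
  }
  structure(out, class = "hf_assignments")
}

sample_assignment <- function(rec) {
  switch(rec$family,
         fixed = rec$base,
         beta = stats::rbeta(1, rec$shape1, rec$shape2),
         gamma = stats::rgamma(1, shape = rec$shape, rate = rec$rate),
         lognormal_rr = stats::rlnorm(1, rec$meanlog, rec$sdlog),
         triangular = rtriangular(1, rec$low, rec$base, rec$high),
         uniform = stats::runif(1, rec$low, rec$high),
         dirichlet_row = {
           if (is.null(rec$alpha)) rec$base else {
             g <- vapply(rec$alpha, function(a)
               if (a <= 0) 0 else stats::rgamma(1, shape = a), 0)
             if (sum(g) <= 0) rec$base else g / sum(g)
           }
         },
         stop("unknown family: ", rec$family))
}

#' Draw one random parameter set from the assignments
#'
#' @param params Base `hf_parameters` (carries fields not covered by the
#'   assignments).
#' @param assignments From [build_assignments()].
#' @return A list with `params` (the sampled `hf_parameters`) and
#'   `clamped` (number of values clamped into their domain).
#' @export
sample_parameter_set <- function(params, assignments) {
  clamped <- 0L
  for (nm in names(assignments)) {
    rec <- assignments[[nm]]
    val <- sample_assignment(rec)
    if (rec$family == "dirichlet_row") {
      if (nm == "init_nyha") {
        params$init_nyha[] <- val
      } else {
        i <- match(sub("^transition\\.", "", nm), NYHA)
        params$transition[i, ] <- val
      }
    } else {
      if (nm %in% c("p_hosp_mdc", "p_death_mdc", "adherence", "avoidance") &&
            (val < 0 || val > 1)) {
        val <- min(max(val, 0), 1)
        clamped <- clamped + 1L
      }
      if (grepl("^utility\\.", nm) && (val < 0 || val > 1)) {
        val <- min(max(val, 0), 1)
        clamped <- clamped + 1L
      }
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(parts) == 1) {
        params[[nm]] <- val
      } else {
        params[[parts[1]]][match(parts[2], NYHA)] <- val
      }
    }
  }
  list(params = params, clamped = clamped)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` full parameter sets from the distribution assignments, runs
#' both strategy arms per draw, and records the incremental cost and QALY
#' pair of telemonitoring versus CUC. Summaries report means with
#' normal-approximation 95% confidence intervals and the fractions of
#' draws in each cost-effectiveness-plane quadrant at the configured
#' willingness to pay.
#'
#' @param params Base `hf_parameters` object.
#' @param config An `hf_config` object (`psa_iterations`, `wtp`,
#'   `rng_seed` defaults come from here).
#' @param n Number of Monte Carlo iterations.
#' @param seed Integer seed; the draw sequence is reproducible for a fixed
#'   seed.
#' @param specs Parameter specification table.
#' @return An object of class `hf_psa`: list with `draws` (data.frame
#'   `iteration`, `delta_cost`, `delta_qaly`, `quadrant`), `summary`
#'   (means, sds, CIs), `quadrant_fractions`, `clamp_rate`, `seed`,
#'   `n_iterations`, `wtp`.
#' @examples
#' \donttest{
#' psa <- run_psa(default_parameters(), n = 200, seed = 1)
#' psa$summary
#' }
#' @export
run_psa <- function(params, config = analysis_config(),
                    n = config$psa_iterations, seed = config$rng_seed,
                    specs = parameter_specs(params)) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  assignments <- build_assignments(specs)
  dc <- dq <- numeric(n)
  clamped <- 0L
  for (i in seq_len(n)) {
    draw <- sample_parameter_set(params, assignments)
    clamped <- clamped + draw$clamped
    cmp <- run_pair(draw$params, config)
    dc[i] <- cmp$delta_cost
    dq[i] <- cmp$delta_qaly
  }
  quadrant <- ifelse(dq > 0 & dc <= 0, "dominant",
              ifelse(dq > 0 & dc > 0 & dc / dq < config$wtp,
                     "icer_below_wtp",
              ifelse(dq > 0, "icer_above_wtp",
              ifelse(dc >= 0, "dominated", "sw_tradeoff"))))
  qf <- vapply(c("dominant", "icer_below_wtp", "icer_above_wtp",
                 "dominated", "sw_tradeoff"),
               function(q) mean(quadrant == q), 0)
  ci <- function(x) {
    se <- stats::sd(x) / sqrt(n)
    c(mean = mean(x), sd = stats::sd(x),
      ci_low = mean(x) - 1.96 * se, ci_high = mean(x) + 1.96 * se)
  }
  summary <- rbind(delta_cost = ci(dc), delta_qaly = ci(dq))
  structure(list(
    draws = data.frame(iteration = seq_len(n), delta_cost = dc,
                       delta_qaly = dq, quadrant = quadrant),
    summary = summary,
    quadrant_fractions = qf,
    clamp_rate = clamped / n,
    seed = seed, n_iterations = n, wtp = config$wtp),
    class = "hf_psa")
}

#' @export
print.hf_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<hf_psa> %d iterations (seed %s)\n", x$n_iterations,
              format(x$seed)))
  cat(sprintf("  mean incremental cost  %8.2f US$  (95%% CI %.2f-%.2f)\n",
              s["delta_cost", "mean"], s["delta_cost", "ci_low"],
              s["delta_cost", "ci_high"]))
  cat(sprintf("  mean incremental QALYs %8.4f      (95%% CI %.4f-%.4f)\n",
              s["delta_qaly", "mean"], s["delta_qaly", "ci_low"],
              s["delta_qaly", "ci_high"]))
  qf <- x$quadrant_fractions
  cat(sprintf("  quadrants at WTP %s: dominant %.1f%%, below-WTP %.1f%%, above-WTP %.1f%%, dominated %.1f%%\n",
              format(x$wtp), 100 * qf["dominant"],
              100 * qf["icer_below_wtp"], 100 * qf["icer_above_wtp"],
              100 * qf["dominated"]))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the telemonitoring arm's probability
#' of being cost-effective is the fraction of PSA iterations with positive
#' incremental net monetary benefit (`wtp * delta_qaly - delta_cost > 0`);
#' CUC receives the complement. Exact ties count for CUC (conservative).
#'
#' @param psa An `hf_psa` object.
#' @param wtp_grid Willingness-to-pay grid, US $ per QALY (default 0 to
#'   100,000 in steps of 500).
#' @return An object of class `hf_ceac`: data.frame with columns `wtp`,
#'   `p_telemonitoring`, `p_cuc`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 500)) {
  stopifnot(nrow(psa$draws) > 0)
  p_tm <- vapply(wtp_grid, function(w)
    mean(w * psa$draws$delta_qaly - psa$draws$delta_cost > 0), 0)
  structure(data.frame(wtp = wtp_grid, p_telemonitoring = p_tm,
                       p_cuc = 1 - p_tm),
            class = c("hf_ceac", "data.frame"))
}

#' WTP at which both strategies are equally likely to be cost-effective
#'
#' Locates the acceptability-curve crossing where each strategy has a 50%
#' probability of being preferred, by linear interpolation between the
#' bracketing grid points.
#'
#' @param ceac_curve An `hf_ceac` object.
#' @return The crossover willingness to pay, or `NA` when the curve does
#'   not cross 0.5 on the grid.
#' @export
ceac_crossover <- function(ceac_curve) {
  p <- ceac_curve$p_telemonitoring - 0.5
  w <- ceac_curve$wtp
  idx <- which(p[-1] * p[-length(p)] <= 0 &
                 (p[-1] != 0 | p[-length(p)] != 0))
  if (length(idx) == 0) {
    if (any(p == 0)) return(w[which(p == 0)[1]])
    return(NA_real_)
  }
  i <- idx[1]
  if (p[i] == p[i + 1]) return((w[i] + w[i + 1]) / 2)
  w[i] + (0 - p[i]) * (w[i + 1] - w[i]) / (p[i + 1] - p[i])
}

#' Write PSA draws or a CEAC as CSV
#'
#' @param x An `hf_psa` or `hf_ceac` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_psa_csv <- function(x, path) {
  df <- if (inherits(x, "hf_psa")) x$draws else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a PSA summary to JSON
#'
#' @param psa An `hf_psa` object.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
psa_to_json <- function(psa, path = NULL) {
  x <- list(n_iterations = psa$n_iterations, seed = psa$seed,
            wtp = psa$wtp,
            mean_delta_cost = unname(psa$summary["delta_cost", "mean"]),
            ci_delta_cost = unname(psa$summary["delta_cost",
                                               c("ci_low", "ci_high")]),
            mean_delta_qaly = unname(psa$summary["delta_qaly", "mean"]),
            ci_delta_qaly = unname(psa$summary["delta_qaly",
                                               c("ci_low", "ci_high")]),
            quadrant_fractions = as.list(psa$quadrant_fractions),
            clamp_rate = psa$clamp_rate)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
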
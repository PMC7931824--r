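# Orchestration: the full analysis bundle and its file exports.

#' Cost of care avoidance: paired short-horizon comparison
#'
#' Runs the multidisciplinary-care arm twice over the avoidance duration
#' (default 1.5 years): once with the configured care-avoidance fraction
#' and once with no avoidance, and reports the cost increase and QALY loss
#' attributable to COVID-19-related care avoidance.
#'
#' @param params An `hf_parameters` object.
#' @param config An `hf_config` object; the horizon is replaced by the
#'   avoidance duration.
#' @return A list with the two `hf_run`s (`with_avoidance`,
#'   `without_avoidance`), `delta_cost` (avoidance minus no-avoidance) and
#'   `qaly_loss` (no-avoidance minus avoidance).
#' @export
avoidance_impact <- function(params, config = analysis_config()) {
  cfg <- config
  cfg$horizon_years <- params$avoidance_duration_years
  p0 <- params
  p0$avoidance <- 0
  with_av <- run_cohort(params, "CUC", cfg)
  without_av <- run_cohort(p0, "CUC", cfg)
  list(with_avoidance = with_av, without_avoidance = without_av,
       delta_cost = with_av$total_cost - without_av$total_cost,
       qaly_loss = without_av$total_qaly - with_av$total_qaly)
}

#' Run the full analysis bundle
#'
#' Base-case two-arm comparison, avoidance-impact comparison, one-way
#' tornado, the two published threshold searches, the two-way
#' risk-ratio grid, and the probabilistic sensitivity analysis with its
#' acceptability curve. When `out_dir` is given, every table is written as
#' CSV and every summary as JSON, together with a provenance block (seed,
#' parameter digest).
#'
#' @param params An `hf_parameters` object.
#' @param config An `hf_config` object.
#' @param out_dir Output directory, or `NULL` to skip file output.
#' @param psa_n PSA iterations (default from `config`).
#' @param grid_n Two-way grid resolution per axis.
#' @param seed Seed for the PSA.
#' @param quiet Suppress progress messages.
#' @return An object of class `hf_report`: list with `basecase`
#'   (`hf_cea` plus the two runs), `avoidance`, `tornado`, `thresholds`,
#'   `twoway`, `psa`, `ceac`, `provenance`.
#' @export
run_report <- function(params = default_parameters(),
                       config = analysis_config(),
                       out_dir = NULL,
                       psa_n = config$psa_iterations,
                       grid_n = 51,
                       seed = config$rng_seed,
                       quiet = FALSE) {
  note <- function(...) if (!quiet) message(sprintf(...))
  note("base case ...")
  cuc <- run_cohort(params, "CUC", config)
  tm <- run_cohort(params, "TM", config)
  cmp <- compare_strategies(cuc, tm, wtp = config$wtp)
  note("avoidance impact ...")
  avoid <- avoidance_impact(params, config)
  note("one-way sensitivity ...")
  tornado <- one_way_dsa(params, config)
  note("threshold searches ...")
  thresholds <- list(
    p_hosp_dominance = threshold_search(params, "p_hosp_mdc",
                                        "dominance_onset", 0.0296, 0.15,
                                        config),
    tm_cost_wtp = threshold_search(params, "tm_monthly_cost",
                                   "wtp_crossing", 50, 2000, config))
  note("two-way grid ...")
  twoway <- two_way_dsa(params, config, grid_n = grid_n)
  note("PSA (%d iterations) ...", psa_n)
  psa <- run_psa(params, config, n = psa_n, seed = seed)
  curve <- ceac(psa)
  prov <- list(seed = seed, psa_n = psa_n, grid_n = grid_n,
               wtp = config$wtp, horizon_years = config$horizon_years,
               parameters = jsonlite::fromJSON(
                 serialize_parameters(params)))
  report <- structure(list(basecase = cmp, runs = list(CUC = cuc, TM = tm),
                           avoidance = avoid, tornado = tornado,
                           thresholds = thresholds, twoway = twoway,
                           psa = psa, ceac = curve, provenance = prov),
                      class = "hf_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.hf_report <- function(x, ...) {
  cat("== Base case ==\n")
  print(x$basecase)
  cat(sprintf("\n== Care-avoidance impact (%.3g years) ==\n",
              nrow(x$avoidance$with_avoidance$trace) / 12))
  cat(sprintf("  added cost %.2f US$, QALY loss %.4f\n",
              x$avoidance$delta_cost, x$avoidance$qaly_loss))
  cat(sprintf("\n== Sensitivity ==\n  critical parameters (>20%% ICER change): %d\n",
              sum(x$tornado$critical)))
  cat(sprintf("  dominance threshold for p_hosp_mdc: %.4f\n",
              x$thresholds$p_hosp_dominance))
  cat(sprintf("  telemonitoring fee WTP threshold: %.0f US$/month\n",
              x$thresholds$tm_cost_wtp))
  cat("\n== PSA ==\n")
  print(x$psa)
  w <- x$ceac$wtp[which.min(abs(x$ceac$wtp - x$psa$wtp))]
  cat(sprintf("  CEAC at WTP %s: %.1f%%; crossover at %.0f US$/QALY\n",
              format(w),
              100 * x$ceac$p_telemonitoring[x$ceac$wtp == w],
              ceac_crossover(x$ceac)))
  invisible(x)
}

#' Write every report artifact to a directory
#'
#' @param report An `hf_report` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  cea_to_json(report$basecase, fp("basecase.json"))
  write_trace_csv(report$runs$CUC, fp("trace_cuc.csv"))
  write_trace_csv(report$runs$TM, fp("trace_tm.csv"))
  jsonlite::write_json(
    list(delta_cost = report$avoidance$delta_cost,
         qaly_loss = report$avoidance$qaly_loss,
         with_avoidance = list(
           cost = report$avoidance$with_avoidance$total_cost,
           qaly = report$avoidance$with_avoidance$total_qaly),
         without_avoidance = list(
           cost = report$avoidance$without_avoidance$total_cost,
           qaly = report$avoidance$without_avoidance$total_qaly)),
    fp("avoidance_impact.json"), auto_unbox = TRUE, digits = NA)
  write_dsa_csv(report$tornado, fp("tornado.csv"))
  jsonlite::write_json(report$thresholds, fp("thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  write_dsa_csv(report$twoway, fp("twoway_grid.csv"))
  write_psa_csv(report$psa, fp("psa_draws.csv"))
  write_psa_csv(report$ceac, fp("ceac.csv"))
  psa_to_json(report$psa, fp("psa_summary.json"))
  jsonlite::write_json(report$provenance, fp("provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
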
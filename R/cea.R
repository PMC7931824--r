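# Incremental cost-effectiveness comparison of two strategy arms.

QALY_TOL <- 1e-12
COST_TOL <- 1e-9

#' Compare two strategy arms
#'
#' Computes incremental cost and QALYs (alternative minus reference), the
#' incremental cost-effectiveness ratio when defined, a dominance
#' classification on the cost-effectiveness plane, and net monetary benefit
#' (`wtp * QALY - cost`) for both arms.
#'
#' Classification: `dominant` when the alternative gains QALYs at lower
#' cost, `dominated` when it loses QALYs at higher cost,
#' `icer_below_wtp`/`icer_above_wtp` in the remaining quadrants according
#' to the net-monetary-benefit comparison at `wtp` (in the
#' more-QALYs-at-higher-cost quadrant this is exactly the ICER-versus-WTP
#' rule), and `equivalent` when both deltas vanish within tolerance
#' (1e-12 QALY, 1e-9 cost). The ICER is reported as a ratio only in the
#' two trade-off quadrants; in the dominant/dominated quadrants the label
#' carries the result and `icer` is `NA`.
#'
#' @param reference,alternative `hf_run` objects from [run_cohort()]
#'   sharing horizon and discounting.
#' @param wtp Willingness-to-pay threshold, US $ per QALY.
#' @return An object of class `hf_cea`: list with `delta_cost`,
#'   `delta_qaly`, `icer`, `dominance`, `nmb_reference`,
#'   `nmb_alternative`, `wtp`.
#' @examples
#' cfg <- analysis_config()
#' p <- default_parameters()
#' compare_strategies(run_cohort(p, "CUC", cfg), run_cohort(p, "TM", cfg))
#' @export
compare_strategies <- function(reference, alternative,
                               wtp = reference$config$wtp) {
  if (!identical(reference$config$horizon_years,
                 alternative$config$horizon_years) ||
        !identical(reference$config$discount_rate_annual,
                   alternative$config$discount_rate_annual))
    stop("runs must share horizon and discounting", call. = FALSE)
  dc <- alternative$total_cost - reference$total_cost
  dq <- alternative$total_qaly - reference$total_qaly
  nmb_ref <- wtp * reference$total_qaly - reference$total_cost
  nmb_alt <- wtp * alternative$total_qaly - alternative$total_cost
  icer <- NA_real_
  if (abs(dq) < QALY_TOL) {
    dominance <- if (abs(dc) < COST_TOL) "equivalent"
    else if (dc < 0) "dominant" else "dominated"
  } else if (dq > 0 && dc < 0) {
    dominance <- "dominant"
  } else if (dq < 0 && dc > 0) {
    dominance <- "dominated"
  } else {
    icer <- dc / dq
    dominance <- if (nmb_alt > nmb_ref) "icer_below_wtp" else
      "icer_above_wtp"
  }
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 dominance = dominance, nmb_reference = nmb_ref,
                 nmb_alternative = nmb_alt, wtp = wtp,
                 reference = reference$strategy,
                 alternative = alternative$strategy),
            class = "hf_cea")
}

#' Preferred strategy under the willingness-to-pay rule
#'
#' The alternative is preferred when it is dominant or when its ICER lies
#' below the willingness-to-pay threshold; the reference is preferred in
#' the mirror cases; equivalent runs tie.
#'
#' @param comparison An `hf_cea` object.
#' @return `"alternative"`, `"reference"`, or `"tie"`.
#' @export
cea_decision <- function(comparison) {
  switch(comparison$dominance,
         dominant = , icer_below_wtp = "alternative",
         dominated = , icer_above_wtp = "reference",
         equivalent = "tie")
}

#' @export
print.hf_cea <- function(x, ...) {
  cat(sprintf("<hf_cea> %s vs %s (WTP %s $/QALY)\n", x$alternative,
              x$reference, format(x$wtp)))
  cat(sprintf("  incremental cost  %9.2f US$\n", x$delta_cost))
  cat(sprintf("  incremental QALYs %9.4f\n", x$delta_qaly))
  if (!is.na(x$icer))
    cat(sprintf("  ICER              %9.0f US$/QALY\n", x$icer))
  cat(sprintf("  classification    %s -> prefer %s\n", x$dominance,
              cea_decision(x)))
  invisible(x)
}

#' Serialize a comparison to JSON
#'
#' @param comparison An `hf_cea` object.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
cea_to_json <- function(comparison, path = NULL) {
  x <- unclass(comparison)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
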
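# Scenario engine: decision-tree evaluation and the closure_model object.

#' Evaluate one scenario of the decision tree
#'
#' Composes the capacity, economics and QALY layers: freed PACU minutes
#' determine additional cases (capped), additional cases feed the
#' contribution-margin delta, and the bleeding-risk reduction yields the
#' QALY gain. Cohort aggregates scale the per-case values by
#' `cases_per_year` without integer rounding of patients.
#'
#' @param p A `closure_params` object.
#' @param scenario A `scenario_spec`.
#' @param uplift_extra_cases Passed to [scenario_contribution_delta()].
#' @return An object of class `scenario_outcome`: scenario, additional
#'   cases per base case (+ cap flag), dwell and saved minutes,
#'   `contribution` (a `contribution_breakdown`), staff-relief fraction,
#'   `qaly` (a `qaly_outcome`), and cohort totals
#'   `contribution_total_eur`, `additional_cases_total`, `qaly_total`.
#' @export
evaluate_scenario <- function(p, scenario, uplift_extra_cases = FALSE) {
  stopifnot(inherits(p, "closure_params"), inherits(scenario, "scenario_spec"))
  cap <- additional_cases(p, scenario)
  contrib <- scenario_contribution_delta(p, scenario, cap$additional_cases,
                                         uplift_extra_cases)
  relief <- staff_relief(p, scenario)
  q <- qaly_gain(p, scenario)
  n <- p$cases_per_year
  structure(list(
    scenario = scenario,
    dwell_minutes_per_case = pacu_dwell_minutes(p, scenario),
    saved_minutes_per_case = cap$saved_minutes,
    additional_cases_per_base_case = cap$additional_cases,
    cap_binding = cap$cap_binding,
    contribution = contrib,
    staff_relief_fraction = relief,
    qaly = q,
    contribution_total_eur = .from_cents(.to_cents(n * contrib$total_delta_eur)),
    additional_cases_total = n * cap$additional_cases,
    qaly_total = n * q$qaly_gain_per_patient
  ), class = "scenario_outcome")
}

#' Evaluate the canonical scenario grid
#'
#' Runs [evaluate_scenario()] over the six canonical scenarios in order
#' (baseline first). Deterministic: identical parameters give identical
#' output.
#'
#' @inheritParams evaluate_scenario
#' @param scenarios List of `scenario_spec` objects; defaults to
#'   [canonical_scenarios()].
#' @return Named list of `scenario_outcome` objects.
#' @export
evaluate_all <- function(p, scenarios = canonical_scenarios(),
                         uplift_extra_cases = FALSE) {
  lapply(scenarios, function(s) evaluate_scenario(p, s, uplift_extra_cases))
}

.outcomes_table <- function(outcomes) {
  data.frame(
    scenario = vapply(outcomes, function(o) o$scenario$label, character(1)),
    device = vapply(outcomes, function(o) o$scenario$device_used, logical(1)),
    day_case = vapply(outcomes, function(o) o$scenario$day_case_billing,
                      logical(1)),
    early_discharge = vapply(outcomes,
                             function(o) o$scenario$early_discharge_process,
                             logical(1)),
    dwell_min = vapply(outcomes, `[[`, numeric(1), "dwell_minutes_per_case"),
    additional_cases = vapply(outcomes, `[[`, numeric(1),
                              "additional_cases_per_base_case"),
    contribution_delta_eur = vapply(outcomes,
                                    function(o) o$contribution$total_delta_eur,
                                    numeric(1)),
    staff_relief_pct = 100 * vapply(outcomes, `[[`, numeric(1),
                                    "staff_relief_fraction"),
    qaly_gain = vapply(outcomes, function(o) o$qaly$qaly_gain_per_patient,
                       numeric(1)),
    row.names = NULL
  )
}

#' Fit the closure-device decision model
#'
#' The central entry point: evaluates the full decision tree for a
#' parameter set and returns a classed model object carrying the scenario
#' outcomes and a results table analogous to the published output table
#' (additional cases, contribution-margin delta, staff relief, QALY gain
#' per scenario).
#'
#' @param p A `closure_params` object (see [model_parameters()] /
#'   [load_parameters()]).
#' @param scenarios Scenario grid; defaults to [canonical_scenarios()].
#' @param uplift_extra_cases Passed to [scenario_contribution_delta()].
#' @return An object of class `closure_model` with components
#'   `parameters`, `outcomes` (named list of `scenario_outcome`) and
#'   `table` (a data frame, one row per scenario).
#' @examples
#' p <- model_parameters(device_unit_cost_eur = 133)
#' m <- closure_model(p)
#' m
#' @export
closure_model <- function(p, scenarios = canonical_scenarios(),
                          uplift_extra_cases = FALSE) {
  outcomes <- evaluate_all(p, scenarios, uplift_extra_cases)
  structure(list(parameters = p,
                 outcomes = outcomes,
                 table = .outcomes_table(outcomes)),
            class = "closure_model")
}

#' @export
print.closure_model <- function(x, digits = 4, ...) {
  cat("Closure-device decision model (per base case vs baseline)\n\n")
  tab <- x$table
  tab$additional_cases <- round(tab$additional_cases, 3)
  tab$staff_relief_pct <- round(tab$staff_relief_pct, 1)
  tab$contribution_delta_eur <- sprintf("%.2f", tab$contribution_delta_eur)
  tab$qaly_gain <- sprintf("%.4f", tab$qaly_gain)
  print(tab[, c("scenario", "additional_cases", "contribution_delta_eur",
                "staff_relief_pct", "qaly_gain")], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.closure_model <- function(x, ...) x$table

#' @export
summary.closure_model <- function(object, ...) {
  structure(list(model = object), class = "summary.closure_model")
}

#' @export
print.summary.closure_model <- function(x, ...) {
  m <- x$model
  print(m$parameters)
  cat("\n")
  print(m)
  dev_scen <- Filter(function(o) o$scenario$device_used, m$outcomes)
  if (length(dev_scen)) {
    cat("\nBreak-even device unit cost (contribution delta = 0):\n")
    for (o in dev_scen) {
      be <- breakeven_device_cost(m$parameters, o$scenario)
      cat(sprintf("  %-6s %.2f EUR\n", o$scenario$label, be))
    }
  }
  invisible(x)
}

#' @export
plot.closure_model <- function(x, ...) {
  tab <- x$table
  old <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(tab$contribution_delta_eur, names.arg = tab$scenario,
                    ylab = "Contribution delta (EUR/case)", las = 2,
                    main = "Economics", ...)
  graphics::barplot(tab$additional_cases, names.arg = tab$scenario,
                    ylab = "Additional cases per base case", las = 2,
                    main = "Throughput", ...)
  invisible(x)
}

#' Write the scenario results table
#'
#' Serializes the model's results table as CSV or a pipe-delimited
#' Markdown table with columns scenario, additional_cases,
#' contribution_delta_eur, staff_relief_pct, qaly_gain.
#'
#' @param model A `closure_model` object.
#' @param path Destination file.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_scenario_table <- function(model, path, format = c("csv", "markdown")) {
  stopifnot(inherits(model, "closure_model"))
  format <- match.arg(format)
  tab <- model$table[, c("scenario", "additional_cases",
                         "contribution_delta_eur", "staff_relief_pct",
                         "qaly_gain")]
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    fmt_row <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")
    lines <- c(
      fmt_row(names(tab)),
      fmt_row(rep("---", ncol(tab))),
      vapply(seq_len(nrow(tab)), function(i) {
        fmt_row(c(tab$scenario[i],
                  sprintf("%.4f", tab$additional_cases[i]),
                  sprintf("%.2f", tab$contribution_delta_eur[i]),
                  sprintf("%.1f", tab$staff_relief_pct[i]),
                  sprintf("%.4f", tab$qaly_gain[i])))
      }, character(1))
    )
    writeLines(lines, path)
  }
  invisible(path)
}
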
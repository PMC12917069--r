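# One-way sweeps, break-even thresholds and probabilistic sensitivity.

.sweepable_outcomes <- c("contribution", "additional_cases", "staff_relief",
                         "qaly")

# fields whose change can break the severe-rate cross-check; sweeps and PSA
# disable the check rather than force users to co-vary the reference
.severe_check_fields <- c("bleed_rate_no_device", "severe_bleed_scaling",
                          "severe_rate_reference")

.extract_outcome <- function(outcome, which) {
  switch(which,
    contribution = outcome$contribution$total_delta_eur,
    additional_cases = outcome$additional_cases_per_base_case,
    staff_relief = outcome$staff_relief_fraction,
    qaly = attr(outcome$qaly, "unrounded")
  )
}

.with_param <- function(p, parameter, value) {
  fields <- unclass(p)
  fields[[parameter]] <- value
  if (parameter %in% .severe_check_fields) {
    fields$severe_rate_reference <- NA
  }
  validate_parameters(fields)
}

#' One-way sensitivity sweep
#'
#' Re-evaluates a scenario at `n` equally spaced values of one numeric
#' parameter, all else fixed, and locates a break-even point (sign change
#' of the outcome, by linear interpolation) if one exists on the grid.
#'
#' @param p A `closure_params` object.
#' @param scenario A `scenario_spec`.
#' @param parameter Name of a numeric parameter field.
#' @param lo,hi Sweep range (`lo < hi`).
#' @param n Number of grid points (>= 2).
#' @param outcome Which outcome to trace: `"contribution"` (EUR, default),
#'   `"additional_cases"`, `"staff_relief"` or `"qaly"` (unrounded).
#' @return An object of class `sensitivity_result` with fields
#'   `parameter`, `grid`, `outcome_name`, `outcomes` and `breakeven`
#'   (`NA` if the outcome does not change sign).
#' @export
one_way_sensitivity <- function(p, scenario, parameter, lo, hi, n = 11,
                                outcome = .sweepable_outcomes) {
  stopifnot(inherits(p, "closure_params"), inherits(scenario, "scenario_spec"))
  outcome <- match.arg(outcome)
  if (!parameter %in% names(.param_defaults()) ||
      !is.numeric(.param_defaults()[[parameter]] %||% p[[parameter]])) {
    stop(sprintf("'%s' is not a numeric model parameter", parameter),
         call. = FALSE)
  }
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    stop("invalid sweep range: need lo < hi", call. = FALSE)
  }
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  grid <- seq(lo, hi, length.out = n)
  values <- vapply(grid, function(v) {
    .extract_outcome(evaluate_scenario(.with_param(p, parameter, v), scenario),
                     outcome)
  }, numeric(1))
  breakeven <- NA_real_
  sgn <- sign(values)
  flip <- which(sgn[-1] * sgn[-n] < 0)
  if (any(sgn == 0)) {
    breakeven <- grid[which(sgn == 0)[1]]
  } else if (length(flip)) {
    i <- flip[1]
    breakeven <- grid[i] + (grid[i + 1] - grid[i]) *
      values[i] / (values[i] - values[i + 1])
  }
  structure(list(parameter = parameter, grid = grid,
                 outcome_name = outcome, outcomes = values,
                 breakeven = breakeven),
            class = "sensitivity_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("One-way sweep of '%s' over [%g, %g] (%d points), outcome: %s\n",
              x$parameter, min(x$grid), max(x$grid), length(x$grid),
              x$outcome_name))
  cat(sprintf("  outcome range [%g, %g]", min(x$outcomes), max(x$outcomes)))
  if (!is.na(x$breakeven)) cat(sprintf("; break-even at %g", x$breakeven))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.sensitivity_result <- function(x, ...) {
  df <- data.frame(x$grid, x$outcomes)
  names(df) <- c(x$parameter, x$outcome_name)
  df
}

#' Break-even device unit cost
#'
#' The unit cost at which a device scenario's contribution delta is
#' exactly zero: the scenario's revenue effects (day-case net uplift, if
#' billed as a day case, plus the margin on additional cases) divided by
#' the expected number of devices per base case (quota times devices per
#' case). Below this cost the device is margin-positive.
#'
#' @param p A `closure_params` object.
#' @param scenario A `scenario_spec` with `device_used = TRUE`.
#' @return Break-even unit cost in EUR, at cent precision.
#' @export
breakeven_device_cost <- function(p, scenario) {
  stopifnot(inherits(p, "closure_params"), inherits(scenario, "scenario_spec"))
  if (!scenario$device_used) {
    stop("break-even device cost is undefined for scenarios without the device",
         call. = FALSE)
  }
  exposure <- p$device_quota * p$devices_per_case
  if (exposure <= 0) {
    stop("break-even device cost is undefined when device_quota * devices_per_case is 0",
         call. = FALSE)
  }
  ac <- additional_cases(p, scenario)$additional_cases
  uplift_c <- if (scenario$day_case_billing) {
    .to_cents(day_case_net_uplift(p))
  } else 0
  extra_c <- .to_cents(ac * marginal_contribution_per_case(p))
  .from_cents(.to_cents((uplift_c + extra_c) / 100 / exposure))
}

# ---- probabilistic sensitivity analysis ------------------------------------

.draw_param <- function(spec, n, field) {
  if (!is.list(spec) || is.null(spec$dist)) {
    stop(sprintf("distribution for '%s' must be a list with a 'dist' element",
                 field), call. = FALSE)
  }
  switch(spec$dist,
    fixed = rep(spec$value, n),
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    gamma = stats::rgamma(n, shape = spec$shape,
                          rate = spec$rate %||% (1 / spec$scale)),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    stop(sprintf("unsupported distribution '%s' for '%s'", spec$dist, field),
         call. = FALSE)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Seeded Monte-Carlo evaluation of a scenario under parameter
#' uncertainty. Each entry of `distributions` names a numeric parameter
#' and gives its sampling distribution: `list(dist = "beta", shape1, shape2)`
#' for fractions, `list(dist = "gamma", shape, rate)` (or `scale`) or
#' `list(dist = "lognormal", meanlog, sdlog)` for money/times, or
#' `list(dist = "fixed", value)` for a degenerate point mass. Draws
#' falling outside a parameter's valid range are an error. Degenerate
#' distributions at the base-case values reproduce the deterministic
#' outcome exactly with zero spread.
#'
#' @param p A `closure_params` object (base case; undrawn parameters stay
#'   at their values in `p`).
#' @param scenario A `scenario_spec`.
#' @param distributions Named list of distribution specs (see Details).
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; identical seeds give identical summaries.
#' @return An object of class `psa_result`: the per-outcome summary data
#'   frame (`mean`, `sd`, `q2.5`, `q97.5`) for the contribution delta,
#'   additional cases, staff relief and unrounded QALY gain, with the raw
#'   draw matrix in attribute `"draws"`.
#' @export
probabilistic_sensitivity <- function(p, scenario, distributions, n_draws,
                                      seed = 1L) {
  stopifnot(inherits(p, "closure_params"), inherits(scenario, "scenario_spec"))
  if (n_draws < 1) stop("'n_draws' must be at least 1", call. = FALSE)
  fields <- names(distributions)
  unknown <- setdiff(fields, names(.param_defaults()))
  if (length(unknown)) {
    stop(sprintf("unknown parameter(s) in distributions: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  set.seed(seed)
  draws <- vapply(fields,
                  function(f) .draw_param(distributions[[f]], n_draws, f),
                  numeric(n_draws))
  draws <- matrix(draws, nrow = n_draws,
                  dimnames = list(NULL, fields))
  out <- matrix(NA_real_, nrow = n_draws, ncol = 4,
                dimnames = list(NULL, c("contribution_delta_eur",
                                        "additional_cases", "staff_relief",
                                        "qaly_gain")))
  base <- unclass(p)
  for (i in seq_len(n_draws)) {
    fi <- base
    fi[fields] <- as.list(draws[i, ])
    if (any(fields %in% .severe_check_fields)) fi$severe_rate_reference <- NA
    # warnings (e.g. a draw with device bleeding above no-device bleeding)
    # are expected when exploring parameter uncertainty
    pi <- tryCatch(suppressWarnings(validate_parameters(fi)),
                   error = function(e) {
      stop(sprintf("draw %d falls outside a parameter's valid range: %s",
                   i, conditionMessage(e)), call. = FALSE)
    })
    o <- evaluate_scenario(pi, scenario)
    out[i, ] <- c(o$contribution$total_delta_eur,
                  o$additional_cases_per_base_case,
                  o$staff_relief_fraction,
                  attr(o$qaly, "unrounded"))
  }
  summary <- data.frame(
    outcome = colnames(out),
    mean = colMeans(out),
    sd = apply(out, 2, stats::sd),
    q2.5 = apply(out, 2, stats::quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(out, 2, stats::quantile, probs = 0.975, names = FALSE),
    row.names = NULL
  )
  structure(summary, class = c("psa_result", "data.frame"), draws = out,
            n_draws = n_draws, seed = seed)
}
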
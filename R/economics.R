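# Monetary arithmetic. All euro amounts are carried internally as integer
# cents (half-up rounding) so the published two-decimal figures are exact.

# half-up euro -> cent conversion; guards against FP noise near .xx5
.to_cents <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9)
}

.from_cents <- function(cents) cents / 100

#' Average revenue of one occupied bed-day
#'
#' Average cost per inpatient stay divided by the average length of stay,
#' truncated to whole euros. Truncation (rather than rounding) is
#' deliberate: 5088 EUR / 7.2 days = 706.67, and the model proceeds with
#' 706 EUR, which in turn yields the exact 564.80 EUR opportunity cost.
#'
#' @param avg_cost_per_stay_eur Average cost of one inpatient stay (EUR).
#' @param avg_los_days Average length of stay in days (> 0).
#' @return Whole-euro bed-day revenue.
#' @examples
#' bed_day_revenue(5088, 7.2) # 706
#' @export
bed_day_revenue <- function(avg_cost_per_stay_eur, avg_los_days) {
  if (!is.numeric(avg_los_days) || avg_los_days <= 0) {
    stop("'avg_los_days' must be positive", call. = FALSE)
  }
  if (avg_cost_per_stay_eur < 0) {
    stop("'avg_cost_per_stay_eur' must be non-negative", call. = FALSE)
  }
  floor(avg_cost_per_stay_eur / avg_los_days + 1e-9)
}

#' Opportunity cost of one freed bed-day
#'
#' Bed-day revenue times the fixed-cost share: a freed bed is assumed to
#' be refilled by an alternative case, so the hospital keeps the revenue
#' net of that case's variable costs (the 20% complement of the 80%
#' fixed-cost share).
#'
#' @param bed_day_revenue_eur Whole-euro bed-day revenue.
#' @param fixed_cost_share Fixed-cost fraction f in \[0, 1\].
#' @return Opportunity cost in EUR, exact to cents.
#' @examples
#' opportunity_cost_per_bed_day(706, 0.8) # 564.80
#' @export
opportunity_cost_per_bed_day <- function(bed_day_revenue_eur,
                                         fixed_cost_share) {
  if (bed_day_revenue_eur < 0) {
    stop("'bed_day_revenue_eur' must be non-negative", call. = FALSE)
  }
  if (fixed_cost_share < 0 || fixed_cost_share > 1) {
    stop("'fixed_cost_share' must lie in [0, 1]", call. = FALSE)
  }
  .from_cents(.to_cents(bed_day_revenue_eur * fixed_cost_share))
}

#' Net revenue uplift of day-case billing
#'
#' Converting a case to day-case billing frees the overnight bed (credited
#' at the bed-day opportunity cost) but incurs the statutory 0.04
#' relative-weight deduction (times the federal base rate) and any
#' configured lower length-of-stay (ugVWD) discount:
#' `opportunity_cost - rw_deduction * base_rate - ugvwd_discount`.
#' With base-case inputs this is 564.80 - 0.04 x 4400 = 388.80 EUR. The
#' result may be negative for unfavourable parameter sets.
#'
#' @param p A `closure_params` object.
#' @return Net uplift in EUR per converted case, exact to cents.
#' @export
day_case_net_uplift <- function(p) {
  stopifnot(inherits(p, "closure_params"))
  cents <- .to_cents(p$opportunity_cost_per_bed_day_eur) -
    .to_cents(p$rw_deduction_115e * p$federal_base_rate_eur) -
    .to_cents(p$ugvwd_discount_eur)
  .from_cents(cents)
}

#' Marginal contribution of one additional case
#'
#' DRG revenue times the marginal contribution-margin rate (infrastructure
#' cost columns of the InEK cost matrix treated as marginal): the margin
#' earned by one extra case run in freed capacity.
#'
#' @param p A `closure_params` object.
#' @return Contribution in EUR per additional case, rounded to cents.
#' @examples
#' p <- model_parameters(device_unit_cost_eur = 133)
#' marginal_contribution_per_case(p) # 1069.21
#' @export
marginal_contribution_per_case <- function(p) {
  stopifnot(inherits(p, "closure_params"))
  .from_cents(.to_cents(p$drg_revenue_eur * p$marginal_margin_rate))
}

#' Expected device cost per base case
#'
#' Zero when the scenario does not use the closure device; otherwise the
#' application quota times devices per case times the unit cost.
#'
#' @param p A `closure_params` object.
#' @param scenario A `scenario_spec`.
#' @return Expected device cost in EUR per base case.
#' @export
device_cost_per_base_case <- function(p, scenario) {
  stopifnot(inherits(p, "closure_params"), inherits(scenario, "scenario_spec"))
  if (!scenario$device_used) return(0)
  .from_cents(.to_cents(p$device_quota * p$devices_per_case *
                          p$device_unit_cost_eur))
}

#' Contribution-margin delta of a scenario
#'
#' Per-base-case change in contribution margin relative to the baseline,
#' decomposed into three terms: the day-case net uplift (applied iff the
#' scenario bills as a day case), the margin on additional cases enabled
#' by freed PACU capacity, and the expected device cost (subtracted iff
#' the device is used). The total is the exact cent-level sum
#' `uplift + extra_case_margin - device_cost`.
#'
#' @param p A `closure_params` object.
#' @param scenario A `scenario_spec`.
#' @param additional_cases Additional cases per base case (>= 0),
#'   typically from [additional_cases()].
#' @param uplift_extra_cases Logical; if `TRUE`, additional cases in
#'   day-case scenarios also earn the day-case net uplift (off by
#'   default: extra cases earn the marginal contribution only).
#' @return An object of class `contribution_breakdown` with fields
#'   `day_case_uplift_eur`, `extra_case_margin_eur`, `device_cost_eur`
#'   and `total_delta_eur`.
#' @examples
#' p <- model_parameters(device_unit_cost_eur = 133)
#' s <- canonical_scenarios()[["3.3"]]
#' scenario_contribution_delta(p, s, 0)$total_delta_eur # 388.80
#' @export
scenario_contribution_delta <- function(p, scenario, additional_cases,
                                        uplift_extra_cases = FALSE) {
  stopifnot(inherits(p, "closure_params"), inherits(scenario, "scenario_spec"))
  if (!is.numeric(additional_cases) || additional_cases < 0) {
    stop("'additional_cases' must be non-negative", call. = FALSE)
  }
  uplift_c <- if (scenario$day_case_billing) {
    .to_cents(day_case_net_uplift(p))
  } else 0
  per_case_margin <- marginal_contribution_per_case(p)
  extra_value <- additional_cases * per_case_margin
  if (uplift_extra_cases && scenario$day_case_billing) {
    extra_value <- extra_value + additional_cases * day_case_net_uplift(p)
  }
  extra_c <- .to_cents(extra_value)
  device_c <- .to_cents(device_cost_per_base_case(p, scenario))
  structure(list(
    day_case_uplift_eur = .from_cents(uplift_c),
    extra_case_margin_eur = .from_cents(extra_c),
    device_cost_eur = .from_cents(device_c),
    total_delta_eur = .from_cents(uplift_c + extra_c - device_c)
  ), class = "contribution_breakdown")
}

#' @export
print.contribution_breakdown <- function(x, ...) {
  cat(sprintf("Contribution delta: %+.2f EUR per base case\n", x$total_delta_eur))
  cat(sprintf("  day-case net uplift   %+9.2f\n", x$day_case_uplift_eur))
  cat(sprintf("  extra-case margin     %+9.2f\n", x$extra_case_margin_eur))
  cat(sprintf("  device cost           %+9.2f\n", -x$device_cost_eur))
  invisible(x)
}
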
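# Model parameter set, validation and YAML/JSON I/O.

.param_defaults <- function() {
  list(
    target_drg = "F50A",
    cases_per_year = 1,
    device_quota = 0.50,
    devices_per_case = 1,
    federal_base_rate_eur = 4400.00,
    drg_revenue_eur = 6102.80,
    device_unit_cost_eur = NULL, # no default: confidential list price
    marginal_margin_rate = 0.1752,
    avg_cost_per_stay_eur = 5088,
    avg_los_days = 7.2,
    fixed_cost_share = 0.8,
    opportunity_cost_per_bed_day_eur = "derive",
    rw_deduction_115e = 0.04,
    ugvwd_discount_eur = 0.0,
    t_discharge_no_device_min = 340,
    t_mobilize_no_device_min = 269,
    t_discharge_device_min = 270,
    t_mobilize_device_min = 109,
    bleed_rate_no_device = 0.242,
    bleed_rate_device = 0.095,
    severe_bleed_scaling = 0.10,
    severe_rate_reference = 0.023,
    qaly_loss_per_severe_bleed = 0.23,
    pacu_slot_minutes = 540,
    throughput_cap = 0.25
  )
}

.fraction_fields <- c(
  "device_quota", "marginal_margin_rate", "fixed_cost_share",
  "bleed_rate_no_device", "bleed_rate_device", "severe_bleed_scaling",
  "severe_rate_reference", "throughput_cap"
)

.money_fields <- c(
  "federal_base_rate_eur", "drg_revenue_eur", "device_unit_cost_eur",
  "avg_cost_per_stay_eur", "ugvwd_discount_eur"
)

.time_fields <- c(
  "t_discharge_no_device_min", "t_mobilize_no_device_min",
  "t_discharge_device_min", "t_mobilize_device_min"
)

.check_scalar_number <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop(sprintf("parameter '%s' must be a single finite number", field),
         call. = FALSE)
  }
  invisible(value)
}

#' Construct a validated model parameter set
#'
#' Builds the full input set of the decision model. Defaults reproduce the
#' published base-case inputs for DRG F50A day-case ablation: DRG revenue
#' 6102.80 EUR at a 4400 EUR federal base rate, a marginal contribution
#' margin of 17.52\%, opportunity cost of a freed bed-day derived as
#' truncated bed-day revenue (5088 EUR / 7.2 days -> 706 EUR) times the 80\%
#' fixed-cost share (564.80 EUR), PACU discharge/mobilization readiness of
#' 340/269 minutes without and 270/109 minutes with the closure device,
#' access-site bleeding rates of 24.2\% vs 9.5\%, and a 0.23 QALY loss per
#' severe groin bleed.
#'
#' The unit cost of the closure device has no default (it is not public);
#' it must always be supplied.
#'
#' @param device_unit_cost_eur Unit cost of one closure device in euros
#'   (required; no default).
#' @param ... Named overrides of any other parameter field. Unknown names
#'   are an error.
#'
#' @details
#' `opportunity_cost_per_bed_day_eur` may be the string `"derive"` (the
#' default), in which case it is computed as
#' `bed_day_revenue(avg_cost_per_stay_eur, avg_los_days) * fixed_cost_share`
#' and stored as a number.
#'
#' Two bleeding-rate conventions appear in the source material: a rounded
#' 24\% and an exact 24.2\% for the no-device arm. The default is 0.242;
#' `severe_rate_reference` (2.3\%) is a cross-check only and validation
#' requires `severe_bleed_scaling * bleed_rate_no_device` to sit within
#' 0.0015 of it. Set `severe_rate_reference = NA` to disable that check,
#' e.g. when sweeping bleeding rates far from the base case.
#'
#' @return An object of class `closure_params`: a named list of validated
#'   parameter values.
#' @seealso [load_parameters()], [canonical_scenarios()], [closure_model()]
#' @examples
#' p <- model_parameters(device_unit_cost_eur = 133)
#' p$opportunity_cost_per_bed_day_eur # 564.80
#' @export
model_parameters <- function(device_unit_cost_eur, ...) {
  if (missing(device_unit_cost_eur) || is.null(device_unit_cost_eur)) {
    stop("parameter 'device_unit_cost_eur' is required and has no default",
         call. = FALSE)
  }
  overrides <- list(...)
  p <- .param_defaults()
  p$device_unit_cost_eur <- device_unit_cost_eur
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) {
      stop(sprintf("unknown parameter(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    p[names(overrides)] <- overrides
  }
  validate_parameters(p)
}

#' Validate a model parameter list
#'
#' Checks every field of a (possibly hand-built) parameter list: fractions
#' in \[0, 1\], money and times non-negative, mobilization times not later
#' than discharge times within each arm, and consistency of the
#' severe-bleed scaling with the reference severe rate. Resolves the
#' `"derive"` sentinel for the bed-day opportunity cost. A violated bound
#' raises an error naming the offending field; a device-arm bleeding rate
#' above the no-device rate only warns.
#'
#' @param p Named list of parameter values (all fields present).
#' @return The validated list, classed `closure_params`, with
#'   `opportunity_cost_per_bed_day_eur` resolved to a number.
#' @export
validate_parameters <- function(p) {
  expected <- names(.param_defaults())
  missing_fields <- setdiff(expected, names(p))
  if (length(missing_fields)) {
    stop(sprintf("missing parameter field(s): %s",
                 paste(missing_fields, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(names(p), expected)
  if (length(unknown)) {
    stop(sprintf("unknown parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  p <- p[expected]

  if (!is.character(p$target_drg) || length(p$target_drg) != 1L) {
    stop("parameter 'target_drg' must be a single character code",
         call. = FALSE)
  }
  for (field in c("cases_per_year", "devices_per_case")) {
    .check_scalar_number(p[[field]], field)
    if (p[[field]] <= 0) {
      stop(sprintf("parameter '%s' must be positive", field), call. = FALSE)
    }
  }
  for (field in .fraction_fields) {
    if (field == "severe_rate_reference" && length(p[[field]]) == 1L &&
        is.na(p[[field]])) next
    .check_scalar_number(p[[field]], field)
    if (p[[field]] < 0 || p[[field]] > 1) {
      stop(sprintf("parameter '%s' must be a fraction in [0, 1]", field),
           call. = FALSE)
    }
  }
  for (field in c(.money_fields, "rw_deduction_115e", .time_fields)) {
    .check_scalar_number(p[[field]], field)
    if (p[[field]] < 0) {
      stop(sprintf("parameter '%s' must be non-negative", field),
           call. = FALSE)
    }
  }
  .check_scalar_number(p$avg_los_days, "avg_los_days")
  if (p$avg_los_days <= 0) {
    stop("parameter 'avg_los_days' must be positive", call. = FALSE)
  }
  .check_scalar_number(p$pacu_slot_minutes, "pacu_slot_minutes")
  if (p$pacu_slot_minutes <= 0) {
    stop("parameter 'pacu_slot_minutes' must be positive", call. = FALSE)
  }
  if (p$t_mobilize_no_device_min > p$t_discharge_no_device_min) {
    stop(paste("parameter 't_mobilize_no_device_min' must not exceed",
               "'t_discharge_no_device_min'"), call. = FALSE)
  }
  if (p$t_mobilize_device_min > p$t_discharge_device_min) {
    stop(paste("parameter 't_mobilize_device_min' must not exceed",
               "'t_discharge_device_min'"), call. = FALSE)
  }
  if (p$bleed_rate_device > p$bleed_rate_no_device) {
    warning(paste("'bleed_rate_device' exceeds 'bleed_rate_no_device':",
                  "the closure device is modelled as harmful"),
            call. = FALSE)
  }
  if (length(p$severe_rate_reference) == 1L &&
      !is.na(p$severe_rate_reference)) {
    implied <- p$severe_bleed_scaling * p$bleed_rate_no_device
    if (abs(implied - p$severe_rate_reference) > 0.0015) {
      stop(sprintf(paste(
        "parameter 'severe_rate_reference' (%.4f) is inconsistent with",
        "severe_bleed_scaling * bleed_rate_no_device (%.4f);",
        "difference exceeds 0.0015 (set severe_rate_reference = NA to",
        "disable this cross-check)"),
        p$severe_rate_reference, implied), call. = FALSE)
    }
  }

  if (identical(p$opportunity_cost_per_bed_day_eur, "derive")) {
    rev_day <- bed_day_revenue(p$avg_cost_per_stay_eur, p$avg_los_days)
    p$opportunity_cost_per_bed_day_eur <-
      opportunity_cost_per_bed_day(rev_day, p$fixed_cost_share)
  } else {
    .check_scalar_number(p$opportunity_cost_per_bed_day_eur,
                         "opportunity_cost_per_bed_day_eur")
    if (p$opportunity_cost_per_bed_day_eur < 0) {
      stop("parameter 'opportunity_cost_per_bed_day_eur' must be non-negative",
           call. = FALSE)
    }
  }

  structure(p, class = "closure_params")
}

#' Read a model parameter file
#'
#' Reads a YAML (canonical) or JSON parameter file, applies named
#' overrides, fills every absent field with the base-case default, and
#' validates the result. All keys are snake_case as in
#' [model_parameters()]; unknown keys are rejected. Because the device
#' unit cost has no default, it must appear in the file or in `overrides`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file is
#'   treated as "all defaults".
#' @param overrides Named list of field values taking precedence over the
#'   file.
#' @return A validated `closure_params` object.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' writeLines("device_quota: 0.5", path)
#' p <- load_parameters(path, overrides = list(device_unit_cost_eur = 133))
#' @export
load_parameters <- function(path, overrides = list()) {
  if (!file.exists(path)) {
    stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop(sprintf("unsupported parameter file extension '%s' (use YAML or JSON)",
                 ext), call. = FALSE)
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    stop(sprintf("parameter file does not parse to a mapping: %s", path),
         call. = FALSE)
  }
  defaults <- .param_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in parameter file: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop(sprintf("unknown override key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    raw[names(overrides)] <- overrides
  }
  p <- defaults
  p[names(raw)] <- raw
  if (is.null(p$device_unit_cost_eur)) {
    stop(paste("'device_unit_cost_eur' must be supplied in the parameter",
               "file or overrides (it has no default)"), call. = FALSE)
  }
  validate_parameters(p)
}

#' Write a model parameter set to file
#'
#' Serializes a validated parameter set as YAML or JSON (chosen by file
#' extension). A write/load round trip returns an identical set.
#'
#' @param p A `closure_params` object.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "closure_params"))
  ext <- tolower(tools::file_ext(path))
  fields <- unclass(p)
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(fields, path),
    json = jsonlite::write_json(fields, path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    stop(sprintf("unsupported parameter file extension '%s' (use YAML or JSON)",
                 ext), call. = FALSE)
  )
  invisible(path)
}

#' @export
print.closure_params <- function(x, ...) {
  cat("Closure-device decision model parameters\n")
  cat(sprintf("  target DRG %s, %g case(s)/year, device quota %.0f%% (%g/case)\n",
              x$target_drg, x$cases_per_year, 100 * x$device_quota,
              x$devices_per_case))
  cat(sprintf("  DRG revenue %.2f EUR, margin %.2f%%, opportunity cost %.2f EUR/bed-day\n",
              x$drg_revenue_eur, 100 * x$marginal_margin_rate,
              x$opportunity_cost_per_bed_day_eur))
  cat(sprintf("  PACU discharge/mobilization: %g/%g min (no device), %g/%g min (device)\n",
              x$t_discharge_no_device_min, x$t_mobilize_no_device_min,
              x$t_discharge_device_min, x$t_mobilize_device_min))
  cat(sprintf("  bleeding %0.1f%% vs %0.1f%%, severe scaling %.2f, QALY loss %.2f\n",
              100 * x$bleed_rate_no_device, 100 * x$bleed_rate_device,
              x$severe_bleed_scaling, x$qaly_loss_per_severe_bleed))
  cat(sprintf("  device unit cost %.2f EUR; slot %g min; throughput cap %.0f%%\n",
              x$device_unit_cost_eur, x$pacu_slot_minutes,
              100 * x$throughput_cap))
  invisible(x)
}

# ---- scenarios --------------------------------------------------------------

#' Define a scenario of the decision tree
#'
#' A scenario is a leaf of the three-lever decision tree: closure device
#' used or not, day-case billing or full inpatient billing, and early
#' discharge from the PACU at mobilization readiness versus discharge
#' readiness.
#'
#' @param label Scenario label (free text; the canonical grid uses
#'   "Basis" and "3.1".."3.5").
#' @param device_used Logical; suture-based closure device in use (at the
#'   configured per-case quota).
#' @param day_case_billing Logical; bill as a day case under section 115e
#'   SGB V (0.04 relative-weight deduction, freed bed-day credited as
#'   opportunity revenue).
#' @param early_discharge_process Logical; release from the PACU at
#'   mobilization readiness instead of discharge readiness.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, device_used, day_case_billing,
                          early_discharge_process) {
  stopifnot(is.character(label), length(label) == 1L,
            is.logical(device_used), length(device_used) == 1L,
            is.logical(day_case_billing), length(day_case_billing) == 1L,
            is.logical(early_discharge_process),
            length(early_discharge_process) == 1L)
  structure(list(label = label,
                 device_used = device_used,
                 day_case_billing = day_case_billing,
                 early_discharge_process = early_discharge_process),
            class = "scenario_spec")
}

#' The canonical six-scenario grid
#'
#' The published decision tree evaluates five interventions against a
#' baseline: "Basis" (no device, inpatient billing, discharge-ready
#' release), 3.1 (device only), 3.2 (device + day-case), 3.3 (day-case
#' only), 3.4 (day-case + early discharge), and 3.5 (all three levers).
#'
#' @return Named list of six `scenario_spec` objects, baseline first.
#' @export
canonical_scenarios <- function() {
  specs <- list(
    scenario_spec("Basis", FALSE, FALSE, FALSE),
    scenario_spec("3.1", TRUE, FALSE, FALSE),
    scenario_spec("3.2", TRUE, TRUE, FALSE),
    scenario_spec("3.3", FALSE, TRUE, FALSE),
    scenario_spec("3.4", FALSE, TRUE, TRUE),
    scenario_spec("3.5", TRUE, TRUE, TRUE)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "label")
  specs
}

#' @export
print.scenario_spec <- function(x, ...) {
  mark <- function(flag) if (flag) "yes" else "no"
  cat(sprintf("Scenario %s: device %s, day-case billing %s, early PACU discharge %s\n",
              x$label, mark(x$device_used), mark(x$day_case_billing),
              mark(x$early_discharge_process)))
  invisible(x)
}
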
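# PACU dwell-time, throughput and staff-relief layer.

# endpoint minutes for one patient class (device TRUE/FALSE) in a scenario
.arm_dwell <- function(p, device, early) {
  if (device) {
    if (early) p$t_mobilize_device_min else p$t_discharge_device_min
  } else {
    if (early) p$t_mobilize_no_device_min else p$t_discharge_no_device_min
  }
}

#' Expected PACU dwell time per case in a scenario
#'
#' The release endpoint is mobilization readiness when the scenario uses
#' the early-discharge process, otherwise discharge readiness. When the
#' closure device is in use, the expected dwell is the quota-weighted mix
#' of the device and no-device patient classes; otherwise it is the
#' no-device class alone.
#'
#' @param p A `closure_params` object.
#' @param scenario A `scenario_spec`.
#' @return Expected dwell time in minutes.
#' @examples
#' p <- model_parameters(device_unit_cost_eur = 133)
#' pacu_dwell_minutes(p, canonical_scenarios()[["Basis"]]) # 340
#' pacu_dwell_minutes(p, canonical_scenarios()[["3.1"]])   # 305
#' @export
pacu_dwell_minutes <- function(p, scenario) {
  stopifnot(inherits(p, "closure_params"), inherits(scenario, "scenario_spec"))
  early <- scenario$early_discharge_process
  t_no <- .arm_dwell(p, FALSE, early)
  if (!scenario$device_used) return(t_no)
  q <- p$device_quota
  q * .arm_dwell(p, TRUE, early) + (1 - q) * t_no
}

# baseline dwell: no device, discharge-ready endpoint (the "Basis" scenario)
.baseline_dwell <- function(p) p$t_discharge_no_device_min

#' Additional cases per base case from freed PACU capacity
#'
#' PACU minutes saved per case against the baseline scenario (no device,
#' release at discharge readiness), divided by the staffed PACU slot
#' length, and clipped at the throughput cap: beyond a 25\% case increase,
#' structural bottlenecks (cath lab, staffing) are assumed to bind.
#'
#' @param p A `closure_params` object.
#' @param scenario A `scenario_spec`.
#' @return List with `additional_cases` (fraction of a case per base
#'   case), `cap_binding` (logical; `TRUE` iff the cap clipped the raw
#'   gain) and `saved_minutes` (minutes saved per case vs baseline).
#' @examples
#' p <- model_parameters(device_unit_cost_eur = 133)
#' additional_cases(p, canonical_scenarios()[["3.5"]]) # capped at 0.25
#' @export
additional_cases <- function(p, scenario) {
  stopifnot(inherits(p, "closure_params"), inherits(scenario, "scenario_spec"))
  saved <- .baseline_dwell(p) - pacu_dwell_minutes(p, scenario)
  raw <- saved / p$pacu_slot_minutes
  capped <- min(raw, p$throughput_cap)
  list(additional_cases = capped,
       cap_binding = raw > p$throughput_cap,
       saved_minutes = saved)
}

#' Relative PACU staff relief of a scenario
#'
#' Minutes of monitoring saved per case, relative to the staffed PACU slot
#' length. Reported unclipped: the throughput cap limits how many extra
#' cases can be run, not how much monitoring effort each case no longer
#' requires.
#'
#' @param p A `closure_params` object.
#' @param scenario A `scenario_spec`.
#' @return Relief as a fraction of a PACU slot (0 when dwell is unchanged).
#' @export
staff_relief <- function(p, scenario) {
  stopifnot(inherits(p, "closure_params"), inherits(scenario, "scenario_spec"))
  saved <- .baseline_dwell(p) - pacu_dwell_minutes(p, scenario)
  saved / p$pacu_slot_minutes
}
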
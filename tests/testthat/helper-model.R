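# Shared fixtures: base-case parameters with an assumed 133 EUR device
# unit cost (the published cost is confidential; 133 EUR is the package's
# documented calibration assumption).

base_params <- function(...) {
  args <- list(...)
  if (!"device_unit_cost_eur" %in% names(args)) {
    args$device_unit_cost_eur <- 133
  }
  do.call(model_parameters, args)
}

scen <- function(label) canonical_scenarios()[[label]]

# independent enumeration oracle: expected dwell over the two patient
# classes (device / no device) weighted by quota
enum_dwell <- function(p, s) {
  classes <- if (s$device_used) c(TRUE, FALSE) else FALSE
  weights <- if (s$device_used) c(p$device_quota, 1 - p$device_quota) else 1
  times <- vapply(classes, function(dev) {
    if (dev) {
      if (s$early_discharge_process) p$t_mobilize_device_min
      else p$t_discharge_device_min
    } else {
      if (s$early_discharge_process) p$t_mobilize_no_device_min
      else p$t_discharge_no_device_min
    }
  }, numeric(1))
  sum(weights * times)
}

# independent enumeration oracle: expected QALY loss in one arm over the
# four outcome classes (bleed x severe)
enum_arm_qaly_loss <- function(bleed_rate, severe_scaling, qaly_loss) {
  p_bleed_severe <- bleed_rate * severe_scaling
  p_bleed_mild <- bleed_rate * (1 - severe_scaling)
  p_none <- 1 - bleed_rate
  p_bleed_severe * qaly_loss + p_bleed_mild * 0 + p_none * 0
}

# bisection oracle for the break-even device cost: locates the sign change
# of the scenario contribution delta in unit cost. Cent rounding makes the
# delta a step function with a flat zero band (width 1 cent / slope); the
# oracle reports the band's center.
bisect_breakeven <- function(p, s, lo = 0, hi = 5000, tol = 1e-6) {
  f <- function(cost) {
    pc <- validate_parameters(modifyList(unclass(p),
                                         list(device_unit_cost_eur = cost)))
    ac <- additional_cases(pc, s)$additional_cases
    scenario_contribution_delta(pc, s, ac)$total_delta_eur
  }
  stopifnot(f(lo) > 0, f(hi) < 0)
  edge <- function(keep_low) {
    a <- lo
    b <- hi
    while (b - a > tol) {
      mid <- (a + b) / 2
      if (keep_low(f(mid))) a <- mid else b <- mid
    }
    (a + b) / 2
  }
  upper <- edge(function(v) v >= 0) # last cost with non-negative delta
  lower <- edge(function(v) v > 0)  # last cost with strictly positive delta
  (upper + lower) / 2
}
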
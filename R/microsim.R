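# Synthetic patient cohorts and patient-level PACU event simulation.
# This layer is the independent computational cross-check of the
# deterministic capacity and QALY layers.

#' Microsimulation configuration
#'
#' @param n_patients Cohort size (>= 1).
#' @param seed Integer seed for cohort generation.
#' @param time_cv Coefficient of variation of the lognormal PACU dwell
#'   times (>= 0; 0 gives every patient exactly the arm mean).
#' @param beds Number of PACU beds (>= 1).
#' @param day_length_minutes Staffed minutes per PACU day.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients, seed = 1L, time_cv = 0.2, beds = 1L,
                       day_length_minutes = 540) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("'n_patients' must be at least 1", call. = FALSE)
  }
  if (!is.numeric(time_cv) || time_cv < 0) {
    stop("'time_cv' must be non-negative", call. = FALSE)
  }
  if (!is.numeric(beds) || beds < 1) {
    stop("'beds' must be at least 1", call. = FALSE)
  }
  if (!is.numeric(day_length_minutes) || day_length_minutes <= 0) {
    stop("'day_length_minutes' must be positive", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 time_cv = time_cv,
                 beds = as.integer(beds),
                 day_length_minutes = day_length_minutes),
            class = "sim_config")
}

#' Generate a synthetic ablation cohort
#'
#' Draws per-patient records under the scenario's stated rates and times:
#' device use is Bernoulli with the application quota (always `FALSE` in
#' no-device scenarios), PACU dwell is lognormal with the patient's arm
#' endpoint mean (mobilization vs discharge readiness, per the scenario)
#' and coefficient of variation `time_cv` (0 degenerates to the exact
#' mean), bleeding is Bernoulli with the arm's bleeding rate, and a
#' severe bleed is a nested Bernoulli draw within bleeds (so severe
#' implies bleed structurally). Fully reproducible from `cfg$seed`.
#'
#' @param p A `closure_params` object.
#' @param scenario A `scenario_spec`.
#' @param cfg A `sim_config`.
#' @return Data frame with columns `id`, `device`, `dwell_minutes`,
#'   `bleed`, `severe_bleed`.
#' @export
generate_cohort <- function(p, scenario, cfg) {
  stopifnot(inherits(p, "closure_params"), inherits(scenario, "scenario_spec"),
            inherits(cfg, "sim_config"))
  n <- cfg$n_patients
  set.seed(cfg$seed)
  device <- if (scenario$device_used) {
    stats::runif(n) < p$device_quota
  } else rep(FALSE, n)
  early <- scenario$early_discharge_process
  mean_dwell <- ifelse(device, .arm_dwell(p, TRUE, early),
                       .arm_dwell(p, FALSE, early))
  if (cfg$time_cv == 0) {
    dwell <- mean_dwell
  } else {
    sigma2 <- log(1 + cfg$time_cv^2)
    dwell <- stats::rlnorm(n, meanlog = log(mean_dwell) - sigma2 / 2,
                           sdlog = sqrt(sigma2))
  }
  bleed_rate <- ifelse(device, p$bleed_rate_device, p$bleed_rate_no_device)
  bleed <- stats::runif(n) < bleed_rate
  severe <- bleed & (stats::runif(n) < p$severe_bleed_scaling)
  data.frame(id = seq_len(n), device = device, dwell_minutes = dwell,
             bleed = bleed, severe_bleed = severe)
}

#' Simulate PACU bed occupancy for a cohort
#'
#' Greedy first-come-first-served assignment of patients to beds over
#' repeated single days: each day every bed offers `day_length_minutes`;
#' patients are placed in cohort order into the first bed with enough
#' remaining minutes; when the patient at the head of the queue no longer
#' fits any bed, the day ends and occupancy resets. Patients whose dwell
#' exceeds the day length can never be placed and are counted as
#' overflow. Deterministic given the cohort order.
#'
#' @param cohort Data frame from [generate_cohort()] (needs column
#'   `dwell_minutes`).
#' @param cfg A `sim_config` (uses `beds` and `day_length_minutes`).
#' @return List with `patients_served`, `overflow`, `days`,
#'   `served_per_day`, `mean_dwell` (served patients) and
#'   `total_bed_minutes`. `patients_served + overflow` equals the cohort
#'   size.
#' @export
simulate_pacu <- function(cohort, cfg) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(cohort),
            nrow(cohort) >= 1, "dwell_minutes" %in% names(cohort))
  dwell <- cohort$dwell_minutes
  day_len <- cfg$day_length_minutes
  fits <- dwell <= day_len
  overflow <- sum(!fits)
  queue <- dwell[fits]
  days <- 0L
  served <- 0L
  total_min <- 0
  while (length(queue)) {
    days <- days + 1L
    bed_rem <- rep(day_len, cfg$beds)
    placed <- 0L
    for (d in queue) {
      b <- which(bed_rem >= d)[1]
      if (is.na(b)) break # strict FCFS: head of queue blocks the day
      bed_rem[b] <- bed_rem[b] - d
      placed <- placed + 1L
      total_min <- total_min + d
    }
    served <- served + placed
    queue <- queue[-seq_len(placed)]
  }
  list(patients_served = served,
       overflow = overflow,
       days = days,
       served_per_day = if (days > 0) served / days else 0,
       mean_dwell = if (served > 0) total_min / served else NA_real_,
       total_bed_minutes = total_min)
}

#' Cross-validate the deterministic model against the microsimulation
#'
#' Generates a cohort, computes simulated analogues of the deterministic
#' quantities, and reports z-scores (simulated minus deterministic over
#' the Monte-Carlo standard error): mean PACU dwell, uncapped throughput
#' gain (saved minutes over the slot length) and the QALY gain from the
#' empirical severe-bleed risk difference between the cohort's device and
#' no-device patients times the QALY loss per severe bleed. For scenarios
#' without the device the QALY row is structurally zero. With
#' `time_cv = 0` the simulated mean dwell equals the deterministic dwell
#' exactly.
#'
#' @param p A `closure_params` object.
#' @param scenario A `scenario_spec`.
#' @param cfg A `sim_config`.
#' @return An object of class `crossvalidation` (a data frame with one
#'   row per quantity: `quantity`, `deterministic`, `simulated`, `se`,
#'   `z`), with the cohort in attribute `"cohort"`.
#' @export
crossvalidate <- function(p, scenario, cfg) {
  cohort <- generate_cohort(p, scenario, cfg)
  n <- nrow(cohort)
  det_dwell <- pacu_dwell_minutes(p, scenario)
  sim_dwell <- mean(cohort$dwell_minutes)
  se_dwell <- stats::sd(cohort$dwell_minutes) / sqrt(n)
  if (!is.finite(se_dwell)) se_dwell <- 0 # single-patient cohort
  z_dwell <- if (se_dwell > 0) (sim_dwell - det_dwell) / se_dwell else 0

  slot <- p$pacu_slot_minutes
  det_gain <- (.baseline_dwell(p) - det_dwell) / slot # uncapped
  sim_gain <- (.baseline_dwell(p) - sim_dwell) / slot
  se_gain <- se_dwell / slot
  z_gain <- if (se_gain > 0) (sim_gain - det_gain) / se_gain else 0

  if (scenario$device_used && any(cohort$device) && any(!cohort$device)) {
    p_no <- mean(cohort$severe_bleed[!cohort$device])
    p_dev <- mean(cohort$severe_bleed[cohort$device])
    n_no <- sum(!cohort$device)
    n_dev <- sum(cohort$device)
    sim_q <- p$qaly_loss_per_severe_bleed * (p_no - p_dev)
    se_q <- p$qaly_loss_per_severe_bleed *
      sqrt(p_no * (1 - p_no) / n_no + p_dev * (1 - p_dev) / n_dev)
    det_q <- attr(qaly_gain(p, scenario), "unrounded")
    z_q <- if (se_q > 0) (sim_q - det_q) / se_q else 0
  } else {
    sim_q <- 0
    se_q <- 0
    det_q <- 0
    z_q <- 0
  }

  res <- data.frame(
    quantity = c("mean_dwell_minutes", "throughput_gain", "qaly_gain"),
    deterministic = c(det_dwell, det_gain, det_q),
    simulated = c(sim_dwell, sim_gain, sim_q),
    se = c(se_dwell, se_gain, se_q),
    z = c(z_dwell, z_gain, z_q)
  )
  structure(res, class = c("crossvalidation", "data.frame"), cohort = cohort)
}

#' Simulate cohorts from a fitted decision model
#'
#' `simulate()` method for `closure_model`: draws `nsim` synthetic
#' cohorts for one scenario of the model.
#'
#' @param object A `closure_model`.
#' @param nsim Number of cohorts.
#' @param seed Base seed; cohort i uses `seed + i - 1`.
#' @param scenario Scenario label (default `"3.1"`).
#' @param n_patients,time_cv Passed to [sim_config()].
#' @param ... Unused.
#' @return A list of cohort data frames (a single data frame if
#'   `nsim = 1`).
#' @export
simulate.closure_model <- function(object, nsim = 1, seed = 1L,
                                   scenario = "3.1", n_patients = 1000,
                                   time_cv = 0.2, ...) {
  specs <- lapply(object$outcomes, `[[`, "scenario")
  labels <- vapply(specs, `[[`, character(1), "label")
  if (!scenario %in% labels) {
    stop(sprintf("unknown scenario label '%s'", scenario), call. = FALSE)
  }
  s <- specs[[match(scenario, labels)]]
  cohorts <- lapply(seq_len(nsim), function(i) {
    generate_cohort(object$parameters, s,
                    sim_config(n_patients, seed = seed + i - 1L,
                               time_cv = time_cv))
  })
  if (nsim == 1) cohorts[[1]] else cohorts
}
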
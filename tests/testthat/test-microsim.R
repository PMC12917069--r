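test_that("zero dwell variation degenerates to the exact arm means", {
  p <- base_params(device_quota = 1)
  cfg <- sim_config(50, seed = 3, time_cv = 0)
  cohort <- generate_cohort(p, scen("3.5"), cfg)
  expect_true(all(cohort$dwell_minutes == 109))
  # no-device scenario ignores the quota entirely
  cohort34 <- generate_cohort(p, scen("3.4"), cfg)
  expect_false(any(cohort34$device))
  expect_true(all(cohort34$dwell_minutes == 269))
})

test_that("cohorts are reproducible from the seed and structurally sound", {
  p <- base_params()
  cfg <- sim_config(500, seed = 11, time_cv = 0.2)
  a <- generate_cohort(p, scen("3.1"), cfg)
  b <- generate_cohort(p, scen("3.1"), cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(p, scen("3.1"), sim_config(500, seed = 12))
  expect_false(identical(a, c2))
  # severe implies bleed; dwell strictly positive
  expect_true(all(!a$severe_bleed | a$bleed))
  expect_true(all(a$dwell_minutes > 0))
  expect_identical(a$id, 1:500)
})

test_that("empirical rates recover the generating parameters within 3 SEs", {
  p <- base_params()
  n <- 40000
  cohort <- generate_cohort(p, scen("3.1"),
                            sim_config(n, seed = 101, time_cv = 0.2))
  # quota
  q_hat <- mean(cohort$device)
  se_q <- sqrt(p$device_quota * (1 - p$device_quota) / n)
  expect_lte(abs(q_hat - p$device_quota), 3 * se_q)
  # arm bleeding rates
  for (arm in c(TRUE, FALSE)) {
    rate <- if (arm) p$bleed_rate_device else p$bleed_rate_no_device
    idx <- cohort$device == arm
    se <- sqrt(rate * (1 - rate) / sum(idx))
    expect_lte(abs(mean(cohort$bleed[idx]) - rate), 3 * se)
  }
  # overall bleed rate matches the quota-weighted mixture
  mix <- p$device_quota * p$bleed_rate_device +
    (1 - p$device_quota) * p$bleed_rate_no_device
  se_mix <- sqrt(mix * (1 - mix) / n)
  expect_lte(abs(mean(cohort$bleed) - mix), 3 * se_mix)
  # severe-within-bleed nesting
  se_sev <- sqrt(p$severe_bleed_scaling * (1 - p$severe_bleed_scaling) /
                   sum(cohort$bleed))
  expect_lte(abs(mean(cohort$severe_bleed[cohort$bleed]) -
                   p$severe_bleed_scaling), 3 * se_sev)
  # arm mean dwell (lognormal mean equals the arm endpoint)
  for (arm in c(TRUE, FALSE)) {
    idx <- cohort$device == arm
    target <- if (arm) 270 else 340
    se_m <- sd(cohort$dwell_minutes[idx]) / sqrt(sum(idx))
    expect_lte(abs(mean(cohort$dwell_minutes[idx]) - target), 3 * se_m)
  }
})

test_that("bed assignment packs a day greedily and conserves patients", {
  # 1 bed, 540-minute day, identical 109-minute dwells: 4 patients per day
  cohort <- data.frame(dwell_minutes = rep(109, 20))
  out <- simulate_pacu(cohort, sim_config(20, beds = 1,
                                          day_length_minutes = 540))
  expect_equal(out$served_per_day, 4)
  expect_equal(out$days, 5)
  expect_equal(out$patients_served + out$overflow, 20)
  expect_equal(out$total_bed_minutes, 20 * 109)

  # a dwell longer than the day can never be placed
  mixed <- data.frame(dwell_minutes = c(100, 600, 100))
  out2 <- simulate_pacu(mixed, sim_config(3, beds = 1,
                                          day_length_minutes = 540))
  expect_equal(out2$overflow, 1)
  expect_equal(out2$patients_served, 2)
})

test_that("adding beds scales daily throughput until the cohort runs out", {
  cohort <- data.frame(dwell_minutes = rep(109, 40))
  one <- simulate_pacu(cohort, sim_config(40, beds = 1,
                                          day_length_minutes = 540))
  two <- simulate_pacu(cohort, sim_config(40, beds = 2,
                                          day_length_minutes = 540))
  expect_gte(two$served_per_day, 2 * one$served_per_day)
  expect_lte(two$days, one$days)
  expect_equal(two$patients_served, 40)
})

test_that("patient conservation holds on random cohorts", {
  p <- base_params()
  for (seed in 1:5) {
    cohort <- generate_cohort(p, scen("3.5"),
                              sim_config(200, seed = seed, time_cv = 0.6))
    out <- simulate_pacu(cohort, sim_config(200, beds = 3,
                                            day_length_minutes = 540))
    expect_equal(out$patients_served + out$overflow, 200)
  }
})

test_that("microsimulation agrees with the deterministic layer (|z| <= 3)", {
  p <- base_params()
  cfg <- sim_config(20000, seed = 21, time_cv = 0.2)
  for (lab in c("3.1", "3.5")) {
    cv <- crossvalidate(p, scen(lab), cfg)
    expect_identical(cv$quantity,
                     c("mean_dwell_minutes", "throughput_gain", "qaly_gain"))
    expect_true(all(abs(cv$z) <= 3), info = lab)
  }
})

test_that("deterministic dwell is reproduced exactly when time_cv = 0", {
  # single-class cohorts (no device mixing): every dwell is the arm mean
  p <- base_params()
  cv <- crossvalidate(p, scen("3.4"), sim_config(5000, seed = 5, time_cv = 0))
  dwell_row <- cv[cv$quantity == "mean_dwell_minutes", ]
  expect_equal(dwell_row$simulated, dwell_row$deterministic,
               tolerance = 1e-12)
  p1 <- base_params(device_quota = 1)
  cv1 <- crossvalidate(p1, scen("3.5"), sim_config(100, seed = 5, time_cv = 0))
  expect_equal(cv1$simulated[1], 109)
})

test_that("no-device scenarios cross-validate with a QALY estimate of zero", {
  p <- base_params()
  cv <- crossvalidate(p, scen("3.4"), sim_config(2000, seed = 9))
  qrow <- cv[cv$quantity == "qaly_gain", ]
  expect_equal(qrow$simulated, 0)
  expect_equal(qrow$deterministic, 0)
  expect_equal(qrow$z, 0)
})

test_that("simulate() on the model draws scenario cohorts", {
  m <- closure_model(base_params())
  one <- simulate(m, nsim = 1, seed = 2, scenario = "3.1", n_patients = 50)
  expect_s3_class(one, "data.frame")
  expect_equal(nrow(one), 50)
  many <- simulate(m, nsim = 3, seed = 2, scenario = "3.1", n_patients = 50)
  expect_length(many, 3)
  expect_identical(many[[1]], one)
  expect_error(simulate(m, scenario = "9.9"), "unknown scenario")
})
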
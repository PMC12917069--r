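test_that("bed-day revenue truncates to whole euros", {
  expect_equal(bed_day_revenue(5088, 7.2), 706)
  expect_equal(bed_day_revenue(7200, 10), 720)
  expect_equal(bed_day_revenue(0, 7.2), 0)
  expect_error(bed_day_revenue(5088, 0), "avg_los_days")
})

test_that("opportunity cost is the fixed-cost share of bed-day revenue", {
  expect_equal(opportunity_cost_per_bed_day(706, 0.8), 564.80)
  expect_equal(opportunity_cost_per_bed_day(706, 1.0), 706.00)
  expect_equal(opportunity_cost_per_bed_day(706, 0.0), 0.00)
  expect_error(opportunity_cost_per_bed_day(706, 1.2), "fixed_cost_share")
})

test_that("day-case net uplift nets the statutory deductions", {
  expect_equal(day_case_net_uplift(base_params()), 388.80)
  p0 <- base_params(rw_deduction_115e = 0)
  expect_equal(day_case_net_uplift(p0), 564.80)
  p_ug <- base_params(ugvwd_discount_eur = 100)
  expect_equal(day_case_net_uplift(p_ug), 288.80)
  # large deductions make the uplift negative, not an error
  p_neg <- base_params(rw_deduction_115e = 0.2)
  expect_lt(day_case_net_uplift(p_neg), 0)
  # independent of every device parameter
  p_dev <- base_params(device_quota = 0.9, devices_per_case = 2)
  p_dev$device_unit_cost_eur <- 999
  expect_equal(day_case_net_uplift(validate_parameters(unclass(p_dev))),
               388.80)
})

test_that("marginal contribution per case is margin times revenue, in cents", {
  expect_equal(marginal_contribution_per_case(base_params()), 1069.21)
  expect_equal(marginal_contribution_per_case(
    base_params(marginal_margin_rate = 0)), 0)
  expect_equal(marginal_contribution_per_case(
    base_params(drg_revenue_eur = 100, marginal_margin_rate = 0.5)), 50.00)
})

test_that("expected device cost per base case follows quota and count", {
  p <- base_params()
  expect_equal(device_cost_per_base_case(p, scen("3.3")), 0)
  expect_equal(device_cost_per_base_case(p, scen("3.1")), 66.50)
  p2 <- base_params(devices_per_case = 2)
  expect_equal(device_cost_per_base_case(p2, scen("3.1")), 133.00)
})

test_that("contribution breakdown sums exactly and matches hand arithmetic", {
  p <- base_params()
  # day-case only: uplift alone
  b33 <- scenario_contribution_delta(p, scen("3.3"), 0)
  expect_equal(b33$total_delta_eur, 388.80)
  expect_equal(b33$device_cost_eur, 0)
  # baseline: every field zero
  b0 <- scenario_contribution_delta(p, scen("Basis"), 0)
  expect_equal(unlist(unclass(b0)), c(day_case_uplift_eur = 0,
                                      extra_case_margin_eur = 0,
                                      device_cost_eur = 0,
                                      total_delta_eur = 0))
  # device only at the rounded throughput of 0.0648:
  # 0.0648 x 1069.21 = 69.28, minus 0.5 x 132.98 = 66.49 -> 2.79
  p3 <- base_params(device_unit_cost_eur = 132.98)
  b31 <- scenario_contribution_delta(p3, scen("3.1"), 0.0648)
  expect_equal(b31$extra_case_margin_eur, 69.28)
  expect_equal(b31$device_cost_eur, 66.49)
  expect_equal(b31$total_delta_eur, 2.79)
  # identity holds at cent precision for every canonical scenario
  for (s in canonical_scenarios()) {
    b <- scenario_contribution_delta(p, s,
                                     additional_cases(p, s)$additional_cases)
    expect_equal(b$total_delta_eur,
                 b$day_case_uplift_eur + b$extra_case_margin_eur -
                   b$device_cost_eur,
                 tolerance = 1e-12)
  }
})

test_that("total delta is affine in device cost with slope -quota x devices", {
  for (quota in c(0.3, 0.5, 1.0)) {
    for (ndev in 1:2) {
      costs <- c(0, 50, 200, 400)
      totals <- vapply(costs, function(cost) {
        p <- model_parameters(device_unit_cost_eur = cost,
                              device_quota = quota, devices_per_case = ndev)
        ac <- additional_cases(p, scen("3.2"))$additional_cases
        scenario_contribution_delta(p, scen("3.2"), ac)$total_delta_eur
      }, numeric(1))
      slopes <- diff(totals) / diff(costs)
      expect_equal(slopes, rep(-quota * ndev, 3), tolerance = 1e-6)
    }
  }
  # slope zero for non-device scenarios
  totals <- vapply(c(0, 500), function(cost) {
    p <- model_parameters(device_unit_cost_eur = cost)
    scenario_contribution_delta(p, scen("3.3"), 0)$total_delta_eur
  }, numeric(1))
  expect_equal(diff(totals), 0)
})

test_that("total delta is non-decreasing in additional cases and margin", {
  p <- base_params()
  s <- scen("3.1")
  ac_grid <- seq(0, 0.25, by = 0.05)
  totals <- vapply(ac_grid, function(ac) {
    scenario_contribution_delta(p, s, ac)$total_delta_eur
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
  margins <- seq(0, 0.3, by = 0.05)
  totals_m <- vapply(margins, function(m) {
    pm <- base_params(marginal_margin_rate = m)
    scenario_contribution_delta(pm, s, 0.1)$total_delta_eur
  }, numeric(1))
  expect_true(all(diff(totals_m) >= 0))
  expect_error(scenario_contribution_delta(p, s, -0.1), "additional_cases")
})

test_that("the extra-case uplift switch adds uplift on additional cases only", {
  p <- base_params()
  s <- scen("3.2")
  ac <- additional_cases(p, s)$additional_cases
  off <- scenario_contribution_delta(p, s, ac)
  on <- scenario_contribution_delta(p, s, ac, uplift_extra_cases = TRUE)
  expect_equal(on$total_delta_eur - off$total_delta_eur,
               round(ac * day_case_net_uplift(p), 2), tolerance = 0.01)
  # no effect outside day-case billing
  s31 <- scen("3.1")
  ac31 <- additional_cases(p, s31)$additional_cases
  expect_equal(scenario_contribution_delta(p, s31, ac31,
                                           uplift_extra_cases = TRUE),
               scenario_contribution_delta(p, s31, ac31))
})
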
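---
title: "Modelling the economics of femoral venous closure after catheter ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the economics of femoral venous closure after catheter ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(closecon)
```

## The decision problem

Catheter ablation of atrial fibrillation is performed through femoral
venous access. Hemostasis is traditionally achieved by manual compression
with a Z-suture and a pressure bandage, which keeps patients in the
post-anesthesia care unit (PACU) and on the ward for hours. Suture-based
vascular closure devices achieve immediate hemostasis, shorten the time to
mobilization and discharge readiness, and reduce access-site bleeding.

`closecon` quantifies, from the hospital's perspective, what that buys
when combined with two organisational levers available in the German DRG
system: billing the case as a day case under §115e SGB V, and releasing
patients from the PACU once they are safe to mobilize rather than once
they are fully discharge-ready. The three binary levers span a decision
tree; the model evaluates six leaves ("Basis" plus five intervention
scenarios) on four outcomes per base case:

* additional cases enabled by freed PACU capacity,
* the contribution-margin delta in euros,
* relative PACU staff relief,
* the QALY gain from averted severe groin bleeds.

## Model structure

### Capacity

Each scenario has an expected PACU dwell per case: the release endpoint is
the mobilization-readiness time under the early-discharge process,
otherwise the discharge-readiness time, and with the device in use the
dwell is the quota-weighted mix of the device and no-device patient
classes. Defaults are 340/269 minutes (discharge/mobilization) without and
270/109 minutes with the device, at a 50 % application quota.

Saved minutes against the baseline (no device, discharge endpoint,
340 min) convert to throughput as `saved / pacu_slot_minutes` with
`pacu_slot_minutes = 540`. The slot length is a calibration constant of
this model, interpreted as one staffed 9-hour PACU slot per case-day; it
is what makes 35 saved minutes correspond to a 6.5 % case increase.
Throughput is capped at `throughput_cap = 0.25`: beyond a 25 % case
increase, cath-lab and staffing bottlenecks are assumed to bind, so the
full-combination scenario reports 0.25 rather than its uncapped 151/540 =
0.28. Staff relief uses the same denominator but is reported unclipped —
the cap limits how many extra cases can be run, not how much monitoring
effort a case no longer needs.

### Economics

All money is carried internally in integer euro cents (half-up rounding)
so the published two-decimal values are exact. Three terms make up the
contribution delta per base case:

* **Day-case net uplift.** Converting to day-case billing frees the
  overnight bed, valued at the opportunity cost of a bed-day, minus the
  statutory 0.04 relative-weight deduction times the federal base rate and
  minus any lower length-of-stay (ugVWD) discount. The bed-day revenue is
  the average cost per stay over the average length of stay *truncated to
  whole euros* (5088 / 7.2 → 706, not 706.67); truncation is deliberate
  because the model's downstream figures (564.80 = 706 × 0.8, and
  388.80 = 564.80 − 0.04 × 4400) are exact only under it. The ugVWD
  discount defaults to 0 € — it is a real feature of DRG F50A day-case
  billing but its magnitude is not public, and the 388.80 € base-case
  uplift implies it contributed nothing there; it stays configurable.
* **Margin on additional cases.** Each extra case earns
  `drg_revenue_eur × marginal_margin_rate` (6102.80 × 17.52 % = 1069.21 €),
  treating the infrastructure-cost columns of the InEK cost matrix as
  marginal. Whether additional cases in day-case scenarios should *also*
  earn the day-case uplift is genuinely ambiguous; the package exposes it
  as the switch `uplift_extra_cases`, default off.
* **Device cost.** Quota × devices-per-case × unit cost, subtracted in
  device scenarios. The unit cost is confidential and therefore has *no
  default*; users must supply one. Around 133 € the device-only scenario
  is roughly cost-neutral, and `breakeven_device_cost()` gives the exact
  zero-margin cost per scenario (138.60 € for the device-only scenario at
  defaults).

### QALYs

Severe groin bleeds carry a 0.23 QALY loss. Severe bleeds are modelled as
a fixed fraction (`severe_bleed_scaling = 0.10`) of all access-site
bleeds, assuming the device's relative risk carries over to severe
events. This scaling was chosen because it simultaneously matches the
2.3 % severe-bleed rate reported for typical post-catheterization
populations (0.10 × 0.242 = 0.0242) and the headline per-patient gain:
0.23 × (0.0242 − 0.0095) = 0.003381, reported as 0.0034 (3.4 per 1000
patients). Applying the relative risk to the 2.3 % directly would give
0.0032 instead. The no-device bleeding rate defaults to the exact 24.2 %
rather than the rounded 24 % that also circulates, for the same reason.
Validation cross-checks `severe_bleed_scaling × bleed_rate_no_device`
against `severe_rate_reference` (tolerance 0.0015); set the reference to
`NA` to explore rates far from the base case.

## A worked base case

```{r base-case}
p <- model_parameters(device_unit_cost_eur = 133)
m <- closure_model(p)
m
```

The day-case-only row reproduces the 388.80 € uplift exactly; the
device-only row shows the 6.5 % case increase and 0.0034 QALY gain; the
full combination hits the 25 % throughput cap. The published contribution
deltas for the combined scenarios (415.00, 572.22 and 661.27 €) are *not*
reproducible from the stated inputs under any composition rule we could
identify — they depend on the confidential device cost and, apparently,
on additional unstated terms — so the package reports the transparent
decomposition above and guards those cells with property-based tests
(affinity in device cost, monotonicity, break-even consistency) instead
of asserting the printed numbers. The same holds for the published
integer staff-relief percentages (7 %/24 %): no single denominator
reproduces all four, so relief is reported as an exact fraction of the
540-minute slot.

## Sensitivity analysis

The published analysis reports that its conclusions were robust under
varied assumptions but not how those were varied; the package realizes
this as explicit machinery with user-supplied ranges. One-way sweeps
re-evaluate a scenario along a grid of one parameter; break-even points
are located by sign change:

```{r sensitivity}
s32 <- canonical_scenarios()[["3.2"]]
one_way_sensitivity(p, s32, "device_unit_cost_eur", 0, 2000, n = 21)
breakeven_device_cost(p, s32)
```

`probabilistic_sensitivity()` adds a seeded Monte-Carlo layer: beta
distributions for fractions, gamma or lognormal for money and times,
degenerate point masses for fixed values. Degenerate distributions
reproduce the deterministic result exactly, which doubles as a
correctness check.

## The microsimulation and what it validates

`generate_cohort()` draws per-patient records under the scenario's
stated rates: device use ~ Bernoulli(quota), access-site bleeding ~
Bernoulli(arm rate), severe bleeding as a nested Bernoulli within bleeds
(so severe ⊆ bleed is structural), and PACU dwell ~ lognormal with the
arm endpoint as mean. Lognormal was chosen because dwell times are
positive and right-skewed; the coefficient-of-variation
parameterization (`time_cv`, default 0.2 in the simulation helpers)
makes `time_cv = 0` collapse to the deterministic model exactly, giving
a clean degenerate-limit test. `simulate_pacu()` runs a strict
first-come-first-served bed assignment over repeated 540-minute days; a
patient who cannot fit any bed ends the day, and only patients whose
dwell exceeds the whole day are overflow, so patients are conserved.

`crossvalidate()` compares simulated against deterministic values of the
mean dwell, the uncapped throughput gain, and the QALY gain recomputed
from the cohort's empirical severe-bleed risk difference, each with a
Monte-Carlo z-score:

```{r crossval}
crossvalidate(p, canonical_scenarios()[["3.1"]],
              sim_config(20000, seed = 1, time_cv = 0.2))
```

Passing cross-validation shows internal consistency of the two
computational routes — it does not validate the model against real
patients. The synthetic cohorts emulate stated means and rates only:
they carry no arrival-time structure tied to cath-lab schedules, no
correlation between bleeding and dwell (a real severe bleed would extend
the stay), and no between-day case-mix variation. The test-suite
problem sizes (cohorts of 20,000–50,000; PSA with a few thousand draws)
were chosen so that three-standard-error comparisons are sharp enough to
catch systematic errors of a fraction of a minute.

## Numerical choices and edge cases

* Euro amounts are integer cents internally; `bed_day_revenue()`
  truncates to whole euros (see above). Reported QALYs round to 4
  decimals per patient and 1 decimal per 1000.
* The break-even device cost divides revenue effects by
  `device_quota × devices_per_case` and is an error when that exposure is
  zero or the scenario lacks the device.
* Validation is total: any input mapping either yields a valid parameter
  set or an error naming the offending field. A device bleeding rate
  above the no-device rate warns rather than fails (it is implausible,
  not impossible).
* Cohort aggregates scale per-case values by `cases_per_year` with no
  integer rounding of patients.

## Limitations

The deterministic layer is workflow-agnostic: it treats the PACU as pure
capacity, without distinguishing pooled from dedicated recovery units,
and assumes every freed bed-day and PACU slot is refilled (beds as the
bottleneck, a waiting list in place). Hospitals where the cath lab or
staffing is the binding constraint will not realize the modelled case
increase; the throughput cap is a blunt guard for that. The QALY layer
values only averted severe bleeds — comfort, pain and long-term
quality-of-life effects are out of scope, as are discounting, multi-DRG
portfolios and payer-perspective accounting.
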
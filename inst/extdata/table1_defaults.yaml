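# Base-case model inputs (published input table). The confidential device
# unit cost is deliberately absent and must be supplied by the user.
target_drg: F50A
cases_per_year: 1
device_quota: 0.50
devices_per_case: 1
federal_base_rate_eur: 4400.00
drg_revenue_eur: 6102.80
marginal_margin_rate: 0.1752
avg_cost_per_stay_eur: 5088
avg_los_days: 7.2
fixed_cost_share: 0.8
opportunity_cost_per_bed_day_eur: derive
rw_deduction_115e: 0.04
ugvwd_discount_eur: 0.0
t_discharge_no_device_min: 340
t_mobilize_no_device_min: 269
t_discharge_device_min: 270
t_mobilize_device_min: 109
bleed_rate_no_device: 0.242
bleed_rate_device: 0.095
severe_bleed_scaling: 0.10
severe_rate_reference: 0.023
qaly_loss_per_severe_bleed: 0.23
pacu_slot_minutes: 540
throughput_cap: 0.25
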
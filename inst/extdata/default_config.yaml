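# Default configuration of the rppdecay synthetic cohort generator.
# Values are the frozen calibration against the published 31-patient cohort
# summaries (POD-3 mean/median RPP volume, POD-5 mean, POD-7 zero fraction,
# BMI mean) under the constraint that the predictive 97.5% upper limit
# decays monotonically over PODs 3-7; intercepts/slopes/effects are on the
# shifted-log scale y = log(volume_mL + 1), slopes are per post-operative day.
# Edit a copy and pass it via `--config` or read_generator_config().
n_patients: 31
seed: ~
pop_intercept_mean: 2.657
pop_slope_mean: -0.3121
sd_intercept: 1.3655
sd_slope: 0.2497
intercept_slope_corr: -0.1386
group_effects:
  normal: 0.0
  overweight: -0.3
  obese: -0.8
residual_sd: 0.8
detection_limit_mL: 0.05
zero_inflation:
  '3': 0.0
  '5': 0.0
  '7': 0.0
followup_rule: conditional
missing_prob: 0.1
pods:
- 3
- 5
- 7
demographics:
  age:
    mean: 66.2
    sd: 6.7
    lower: 40.0
    upper: 90.0
  height_cm:
    mean: 177.2
    sd: 6.1
    lower: 150.0
    upper: 210.0
  bmi:
    mean: 26.5293
    sd: 4.1
    lower: 16.0
    upper: 45.0
  op_duration_min:
    mean: 302.4
    sd: 43.4
    lower: 120.0
    upper: 600.0
  insufflation_min:
    mean: 278.9
    sd: 42.3
    lower: 100.0
    upper: 600.0
  total_gas_L:
    mean: 971.45
    sd: 426.2
    lower: 50.0
    upper: 3000.0
  decompression_prob:
  - 0.935483870968
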
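# Small in-code fixtures used across the suite.

make_patients <- function(n, bmi = rep(26, n)) {
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = 60 + seq_len(n) %% 10,
    height_cm = 175,
    bmi = bmi,
    weight_kg = bmi * (175 / 100)^2,
    bmi_group = assign_bmi_group(bmi),
    op_duration_min = 300,
    insufflation_min = 280,
    total_gas_L = 900,
    decompressed = TRUE
  )
}

# volumes: data frame with patient (integer), pod, volume_mL
make_cohort <- function(volumes, n = max(volumes$patient), bmi = rep(26, n)) {
  m <- tibble::tibble(
    patient_id = sprintf("P%03d", volumes$patient),
    pod = as.integer(volumes$pod),
    volume_mL = volumes$volume_mL,
    censored = volumes$volume_mL == 0
  )
  rpp_cohort(make_patients(n, bmi), m)
}

# fast sampler settings for unit-level fits
quick_settings <- function(chains = 2, iter = 500) {
  sampler_settings(chains = chains, adapt = 300, warmup = 400, iter = iter)
}

default_true_params <- function() {
  cfg <- generator_config()
  model_params(
    mu_alpha = cfg$pop_intercept_mean, mu_beta = cfg$pop_slope_mean,
    sigma_alpha = cfg$sd_intercept, sigma_beta = cfg$sd_slope,
    rho = cfg$intercept_slope_corr,
    delta = cfg$group_effects[["overweight"]],
    eta = cfg$group_effects[["obese"]],
    sigma_y = cfg$residual_sd
  )
}
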
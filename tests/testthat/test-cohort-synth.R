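test_that("generator config validation names the offending field", {
  expect_error(generator_config(n_patients = 0), "n_patients")
  expect_error(generator_config(sd_intercept = -1), "sd_intercept")
  expect_error(generator_config(intercept_slope_corr = 1.5), "intercept_slope_corr")
  expect_error(generator_config(detection_limit_mL = 0), "detection_limit_mL")
  expect_error(generator_config(zero_inflation = c(`3` = -0.1)), "zero_inflation")
  expect_error(generator_config(followup_rule = "sometimes"))
})

test_that("BMI groups follow the WHO cutoffs", {
  expect_equal(as.character(assign_bmi_group(c(24.99, 25, 29.99, 30, 26.59))),
               c("normal", "overweight", "overweight", "obese", "overweight"))
  expect_error(assign_bmi_group(0), "positive")
  expect_error(assign_bmi_group(-3), "positive")
})

test_that("with all noise off every volume equals the group mean volume", {
  cfg <- generator_config(
    n_patients = 60, sd_intercept = 0, sd_slope = 0, residual_sd = 0,
    pop_slope_mean = 0, zero_inflation = c(`3` = 0, `5` = 0, `7` = 0),
    followup_rule = "complete")
  ch <- simulate_cohort(cfg, seed = 7)
  joined <- dplyr::left_join(ch$measurements,
                             ch$patients[c("patient_id", "bmi_group")],
                             by = "patient_id")
  expected <- exp(cfg$pop_intercept_mean +
                    cfg$group_effects[as.character(joined$bmi_group)]) - 1
  expect_equal(joined$volume_mL, unname(expected), tolerance = 1e-12)
  # identical across PODs within patient
  per_pat <- tapply(joined$volume_mL, joined$patient_id, function(v) diff(range(v)))
  expect_true(all(per_pat == 0))
})

test_that("simulation is deterministic given config and seed, byte for byte", {
  cfg <- generator_config(n_patients = 40, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in c("patients.csv", "measurements.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(a, simulate_cohort(cfg, seed = 12)))
})

test_that("conditional follow-up removes scans after the first zero reading", {
  # 10 patients; patients 1-3 read zero at POD 3
  vols <- expand.grid(patient = 1:10, pod = c(3, 5, 7))
  vols$volume_mL <- ifelse(vols$patient <= 3 & vols$pod == 3, 0,
                           10 + vols$patient)
  ch <- make_cohort(vols)
  out <- apply_followup_rule(ch, "conditional")
  pod5 <- out$measurements[out$measurements$pod == 5, ]
  expect_equal(nrow(pod5), 7)
  expect_false(any(sprintf("P%03d", 1:3) %in%
                     out$measurements$patient_id[out$measurements$pod > 3]))
  # a zero at POD 5 removes POD 7 only
  vols2 <- data.frame(patient = rep(1, 3), pod = c(3, 5, 7),
                      volume_mL = c(5, 0, 4))
  out2 <- apply_followup_rule(make_cohort(vols2), "conditional")
  expect_equal(out2$measurements$pod, c(3L, 5L))
  # complete is the identity
  expect_identical(apply_followup_rule(ch, "complete")$measurements,
                   ch$measurements)
  expect_error(apply_followup_rule(ch, "always"))
})

test_that("cohort invariants are enforced", {
  p <- make_patients(2)
  bad_ref <- tibble::tibble(patient_id = "P999", pod = 3L, volume_mL = 1,
                            censored = FALSE)
  expect_error(rpp_cohort(p, bad_ref), "unknown patient")
  bad_flag <- tibble::tibble(patient_id = "P001", pod = 3L, volume_mL = 0,
                             censored = FALSE)
  expect_error(rpp_cohort(p, bad_flag), "censored")
  dup <- tibble::tibble(patient_id = c("P001", "P001"), pod = c(3L, 3L),
                        volume_mL = c(1, 2), censored = c(FALSE, FALSE))
  expect_error(rpp_cohort(p, dup), "one measurement")
  neg <- tibble::tibble(patient_id = "P001", pod = 3L, volume_mL = -1,
                        censored = FALSE)
  expect_error(rpp_cohort(p, neg), "non-negative")
})

test_that("transformed moments converge to the closed-form law", {
  # noise levels chosen so the back-transform floor is never hit
  params <- model_params(mu_alpha = 3, mu_beta = -0.2, sigma_alpha = 0.3,
                         sigma_beta = 0.1, rho = 0.5, sigma_y = 0.2)
  cfg <- generator_config(
    n_patients = 40000, pop_intercept_mean = 3, pop_slope_mean = -0.2,
    sd_intercept = 0.3, sd_slope = 0.1, intercept_slope_corr = 0.5,
    residual_sd = 0.2, group_effects = c(normal = 0, overweight = 0, obese = 0),
    detection_limit_mL = 1e-9, followup_rule = "complete")
  ch <- simulate_cohort(cfg, seed = 3)
  for (pod in c(3, 5, 7)) {
    v <- ch$measurements$volume_mL[ch$measurements$pod == pod]
    y <- log_shift(v)
    cf <- closed_form_predictive(params, "normal", pod)
    n <- length(y)
    expect_lt(abs(mean(y) - cf$mean), 4 * sqrt(cf$variance / n))
    # chi-square-based tolerance for the sample variance
    expect_lt(abs(var(y) - cf$variance), 5 * cf$variance * sqrt(2 / (n - 1)))
  }
})

test_that("median volume decays monotonically and BMI groups are ordered", {
  ch <- simulate_cohort(generator_config(n_patients = 20000,
                                         followup_rule = "complete"), seed = 9)
  med <- tapply(ch$measurements$volume_mL, ch$measurements$pod, median)
  expect_true(all(diff(med) < 0))
  joined <- dplyr::left_join(ch$measurements[ch$measurements$pod == 3, ],
                             ch$patients[c("patient_id", "bmi_group")],
                             by = "patient_id")
  m3 <- tapply(joined$volume_mL, joined$bmi_group, mean)
  expect_true(m3[["obese"]] < m3[["overweight"]])
  expect_true(m3[["overweight"]] < m3[["normal"]])
})

test_that("zero inflation adds zeros on top of structural censoring", {
  cfg0 <- generator_config(n_patients = 20000, followup_rule = "complete")
  cfg1 <- generator_config(n_patients = 20000,
                           zero_inflation = c(`3` = 0.5, `5` = 0.5, `7` = 0.5),
                           followup_rule = "complete")
  z0 <- mean(simulate_cohort(cfg0, seed = 5)$measurements$volume_mL[
    simulate_cohort(cfg0, seed = 5)$measurements$pod == 3] == 0)
  ch1 <- simulate_cohort(cfg1, seed = 5)
  z1 <- mean(ch1$measurements$volume_mL[ch1$measurements$pod == 3] == 0)
  expect_equal(z1, 0.5 + 0.5 * z0, tolerance = 0.02)
})

test_that("cohort CSV round-trips and the shipped YAML matches the defaults", {
  ch <- simulate_cohort(generator_config(n_patients = 15, seed = 2))
  d <- withr::local_tempdir()
  write_cohort(ch, d)
  back <- read_cohort(d)
  expect_equal(back$patients, ch$patients, tolerance = 1e-12)
  expect_equal(back$measurements, ch$measurements, tolerance = 1e-12)

  path <- system.file("extdata", "default_config.yaml", package = "rppdecay")
  cfg <- read_generator_config(path)
  ref <- generator_config()
  expect_equal(unclass(cfg), unclass(ref), tolerance = 1e-8)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, f)
  expect_equal(unclass(read_generator_config(f)), unclass(ref), tolerance = 1e-8)
})

test_that("demographics reproduce the published means at large n", {
  ch <- simulate_cohort(generator_config(n_patients = 50000), seed = 13)
  p <- ch$patients
  expect_equal(mean(p$bmi), 26.59, tolerance = 0.06)
  expect_equal(mean(p$age), 66.2, tolerance = 0.15)
  expect_equal(mean(p$height_cm), 177.2, tolerance = 0.15)
  expect_equal(mean(p$weight_kg), 83.3, tolerance = 0.5)
  expect_equal(p$bmi, p$weight_kg / (p$height_cm / 100)^2, tolerance = 1e-10)
  expect_equal(mean(p$decompressed), 29 / 31, tolerance = 0.01)
})
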
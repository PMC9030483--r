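test_that("summary rows reproduce hand arithmetic and availability counts", {
  vols <- data.frame(patient = 1:3, pod = 3, volume_mL = c(1, 2, 3))
  ch <- make_cohort(vols)
  tab1 <- summarize_cohort(ch, pods = 3)
  r <- tab1[tab1$variable == "rpp_pod3_mL", ]
  expect_equal(r$n, 3L)
  expect_equal(r$mean, 2)
  expect_equal(r$median, 2)
  expect_equal(r$sd, 1)
  expect_equal(c(r$iqr_low, r$iqr_high), c(1.5, 2.5))  # type-7 quantiles
  # a missing covariate value reduces n for that row only
  ch$patients$age[2] <- NA
  tab2 <- summarize_cohort(ch, pods = 3)
  expect_equal(tab2$n[tab2$variable == "age"], 2L)
  expect_equal(tab2$n[tab2$variable == "bmi"], 3L)
  expect_error(summarize_cohort(rpp_cohort(make_patients(0),
    tibble::tibble(patient_id = character(), pod = integer(),
                   volume_mL = double(), censored = logical()))), "no patients")
})

test_that("summaries are invariant to row order and impute resolved scans as zero", {
  ch <- simulate_cohort(generator_config(n_patients = 200), seed = 14)
  perm <- rpp_cohort(ch$patients[sample(nrow(ch$patients)), ],
                     ch$measurements[sample(nrow(ch$measurements)), ])
  expect_equal(summarize_cohort(perm), summarize_cohort(ch))
  # a patient resolved at POD 3 contributes 0 at PODs 5 and 7
  vols <- data.frame(patient = c(1, 2, 2), pod = c(3, 3, 5),
                     volume_mL = c(0, 8, 4))
  tab1 <- summarize_cohort(make_cohort(vols, n = 2), pods = c(3, 5))
  r5 <- tab1[tab1$variable == "rpp_pod5_mL", ]
  expect_equal(r5$n, 2L)
  expect_equal(r5$mean, 2)  # (0 + 4) / 2
})

test_that("one-way ANOVA matches textbook arithmetic", {
  # identical volume sets in every group: no between-group variance
  vols <- expand.grid(patient = 1:4, pod = c(3, 5, 7))
  vols$volume_mL <- 3 + vols$patient
  a0 <- anova_rpp(make_cohort(vols, n = 4), scale = "raw")
  expect_equal(a0$f_statistic, 0)
  expect_equal(a0$p_value, 1)
  # two groups: F equals the squared pooled t statistic
  vols2 <- data.frame(patient = rep(1:5, 2), pod = rep(c(3, 5), each = 5),
                      volume_mL = c(5, 7, 9, 6, 8, 2, 3, 5, 4, 1))
  a2 <- anova_rpp(make_cohort(vols2, n = 5), scale = "raw")
  tt <- t.test(c(5, 7, 9, 6, 8), c(2, 3, 5, 4, 1), var.equal = TRUE)
  expect_equal(a2$f_statistic, unname(tt$statistic)^2)
  expect_equal(a2$p_value, tt$p.value)
  # 3 x 3 fixture against explicit sums of squares
  vols3 <- data.frame(patient = rep(1:3, 3), pod = rep(c(3, 5, 7), each = 3),
                      volume_mL = c(1, 2, 3, 2, 3, 4, 0, 1, 2))
  a3 <- anova_rpp(make_cohort(vols3, n = 3), scale = "raw")
  ssb <- 3 * ((2 - 2)^2 + (3 - 2)^2 + (1 - 2)^2)
  ssw <- sum((c(1, 2, 3) - 2)^2) + sum((c(2, 3, 4) - 3)^2) +
    sum((c(0, 1, 2) - 1)^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(a3$f_statistic, f_hand)
  expect_equal(a3$df_between, 2L)
  expect_equal(a3$df_within, 6L)
  expect_equal(a3$p_value, pf(f_hand, 2, 6, lower.tail = FALSE))
  # insufficient groups
  expect_error(anova_rpp(make_cohort(data.frame(patient = 1:3, pod = 3,
                                                volume_mL = 1:3))),
               "at least 2 PODs")
})

test_that("correlation matrix is symmetric with unit diagonal; exact anticorrelation", {
  n <- 6
  p <- make_patients(n)
  p$op_duration_min <- 500 - p$age  # exact linear anticorrelation with age
  m <- tibble::tibble(patient_id = p$patient_id, pod = 3L,
                      volume_mL = seq(2, 12, length.out = n), censored = FALSE)
  cm <- suppressWarnings(correlation_matrix(rpp_cohort(p, m)))
  expect_true(isSymmetric(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, ncol(cm$r)))
  expect_equal(cm$r["age", "op_duration_min"], -1)
  td <- tidy(cm)
  expect_true(all(td$estimate >= -1 & td$estimate <= 1, na.rm = TRUE))
  # constant variable is flagged, not zeroed
  expect_warning(correlation_matrix(rpp_cohort(p, m)), "constant")
  expect_true(all(is.na(cm$r["height_cm", setdiff(colnames(cm$r), "height_cm")])))
})

test_that("generated cohorts encode the negative BMI-RPP correlation", {
  ch <- simulate_cohort(generator_config(n_patients = 5000), seed = 20)
  cm <- suppressWarnings(correlation_matrix(ch))
  expect_lt(cm$r["bmi", "rpp_pod3_mL"], 0)
  expect_lt(cm$p["bmi", "rpp_pod3_mL"], 0.01)
  sp <- suppressWarnings(correlation_matrix(ch, method = "spearman"))
  expect_lt(sp$r["bmi", "rpp_pod3_mL"], 0)
})

test_that("zero-RPP fraction counts resolved patients as zero", {
  vols <- data.frame(patient = 1:31, pod = 3,
                     volume_mL = c(rep(0, 10), rep(5, 21)))
  ch <- make_cohort(vols, n = 31)
  expect_equal(zero_rpp_fraction(ch, 3), 10 / 31, tolerance = 1e-10)
  expect_equal(round(zero_rpp_fraction(ch, 3), 4), 0.3226)
  # the 10 resolved patients count as zero at POD 5 even with no scan rows
  vols5 <- rbind(vols, data.frame(patient = 11:31, pod = 5, volume_mL = 5))
  ch5 <- make_cohort(vols5, n = 31)
  expect_equal(zero_rpp_fraction(ch5, 5), 10 / 31)
  all_zero <- make_cohort(data.frame(patient = 1:4, pod = 3, volume_mL = 0))
  expect_equal(zero_rpp_fraction(all_zero, 3), 1)
  none_zero <- make_cohort(data.frame(patient = 1:4, pod = 3, volume_mL = 2))
  expect_equal(zero_rpp_fraction(none_zero, 3), 0)
  expect_error(zero_rpp_fraction(none_zero, 9), "no information")
})

test_that("zero fraction rises across PODs under the default calibration", {
  ch <- simulate_cohort(generator_config(n_patients = 20000), seed = 25)
  z <- vapply(c(3, 5, 7), function(d) zero_rpp_fraction(ch, d), numeric(1))
  expect_true(all(diff(z) > 0))
})
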
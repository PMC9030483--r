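#' Construct a cohort object
#'
#' A cohort bundles a patient table (one row per patient, demographic and
#' operative covariates) and a long measurement table (one row per performed
#' CT scan). Both are tibbles; all analysis functions in the package take a
#' cohort (or the two tibbles) and return tibbles.
#'
#' @param patients Tibble with columns `patient_id`, `age`, `weight_kg`,
#'   `height_cm`, `bmi`, `bmi_group`, `op_duration_min`, `insufflation_min`,
#'   `total_gas_L`, `decompressed`.
#' @param measurements Tibble with columns `patient_id`, `pod`, `volume_mL`,
#'   `censored`.
#' @return An object of class `"rpp_cohort"`.
#' @export
rpp_cohort <- function(patients, measurements) {
  obj <- structure(
    list(patients = as_tibble(patients), measurements = as_tibble(measurements)),
    class = "rpp_cohort"
  )
  validate_cohort(obj)
}

#' Validate a cohort object
#'
#' Checks referential integrity (every measurement belongs to a known
#' patient), the censoring convention (`censored` is true exactly when
#' `volume_mL == 0`), non-negative volumes, and uniqueness of
#' (patient, POD) rows.
#'
#' @param cohort An `"rpp_cohort"`.
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$patients
  m <- cohort$measurements
  need_p <- c("patient_id", "bmi", "bmi_group")
  if (!all(need_p %in% names(p))) {
    abort(sprintf("patients table must contain columns: %s",
                  paste(setdiff(need_p, names(p)), collapse = ", ")))
  }
  need_m <- c("patient_id", "pod", "volume_mL", "censored")
  if (!all(need_m %in% names(m))) {
    abort(sprintf("measurements table must contain columns: %s",
                  paste(setdiff(need_m, names(m)), collapse = ", ")))
  }
  if (!all(m$patient_id %in% p$patient_id)) {
    abort("measurement rows reference unknown patient_id values")
  }
  if (any(m$volume_mL < 0)) abort("volume_mL must be non-negative")
  if (!identical(m$censored, m$volume_mL == 0)) {
    abort("censored flag must be TRUE exactly when volume_mL == 0")
  }
  if (anyDuplicated(m[c("patient_id", "pod")]) > 0) {
    abort("at most one measurement per (patient_id, pod)")
  }
  invisible(cohort)
}

#' @export
print.rpp_cohort <- function(x, ...) {
  cat(sprintf("<rpp_cohort> %d patients, %d measurements (PODs %s)\n",
              nrow(x$patients), nrow(x$measurements),
              paste(sort(unique(x$measurements$pod)), collapse = ", ")))
  invisible(x)
}

#' Classify body-mass index into WHO groups
#'
#' Normal weight below 25 kg/m², overweight in \[25, 30), obese at or above
#' 30 kg/m².
#'
#' @param bmi Numeric vector of BMI values (kg/m²), all positive.
#' @return A factor with levels `normal`, `overweight`, `obese`.
#' @export
#' @examples
#' assign_bmi_group(c(24.99, 25, 30))
assign_bmi_group <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    abort("bmi must be positive and finite")
  }
  cut(bmi, breaks = c(0, 25, 30, Inf), labels = BMI_GROUPS, right = FALSE)
}

#' Simulate a synthetic RPP cohort
#'
#' Draws patient demographics, patient-level random intercepts and slopes from
#' the bivariate normal population law, latent shifted-log volumes
#' `y = alpha_j + beta_j * (POD - 3) + group effect + noise` at each scheduled
#' scan day, back-transforms to volumes `V = exp(y) - 1` (floored at zero),
#' applies zero inflation and detection-limit censoring, and finally the
#' follow-up rule. Fully deterministic given the seed.
#'
#' @param config An [generator_config()] object.
#' @param n_patients Optional override of `config$n_patients`.
#' @param seed Optional override of `config$seed`.
#' @return An [rpp_cohort()] object.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(n_patients = 20, seed = 42))
#' cohort$measurements
simulate_cohort <- function(config = generator_config(),
                            n_patients = NULL, seed = NULL) {
  config <- validate_generator_config(config)
  n <- as.integer(n_patients %||% config$n_patients)
  seed <- seed %||% config$seed
  with_seed_if(seed, {
    patients <- simulate_patients(config, n)
    measurements <- simulate_measurements(config, patients)
    cohort <- rpp_cohort(patients, measurements)
    apply_followup_rule(cohort, config$followup_rule, config$missing_prob)
  })
}

simulate_patients <- function(config, n) {
  d <- config$demographics
  draw <- function(spec) rtruncnorm(n, spec[["mean"]], spec[["sd"]],
                                    spec[["lower"]], spec[["upper"]])
  height <- draw(d$height_cm)
  bmi <- draw(d$bmi)
  tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = draw(d$age),
    height_cm = height,
    bmi = bmi,
    weight_kg = bmi * (height / 100)^2,
    bmi_group = assign_bmi_group(bmi),
    op_duration_min = draw(d$op_duration_min),
    insufflation_min = draw(d$insufflation_min),
    total_gas_L = draw(d$total_gas_L),
    decompressed = runif(n) < d$decompression_prob
  )
}

simulate_measurements <- function(config, patients) {
  n <- nrow(patients)
  pods <- config$pods
  # correlated random effects (alpha_j, beta_j)
  za <- rnorm(n)
  zb <- rnorm(n)
  rho <- config$intercept_slope_corr
  alpha <- config$pop_intercept_mean + config$sd_intercept * za
  beta <- config$pop_slope_mean +
    config$sd_slope * (rho * za + sqrt(1 - rho^2) * zb)
  eff <- unname(config$group_effects[as.character(patients$bmi_group)])

  long <- crossing(
    tibble(patient_id = patients$patient_id, alpha = alpha, beta = beta,
           eff = eff),
    tibble(pod = pods)
  )
  zi <- config$zero_inflation[as.character(long$pod)]
  zi[is.na(zi)] <- 0
  y <- long$alpha + long$beta * (long$pod - 3) + long$eff +
    rnorm(nrow(long), 0, config$residual_sd)
  vol <- pmax(exp(y) - 1, 0)
  vol[runif(nrow(long)) < zi] <- 0
  vol[vol < config$detection_limit_mL] <- 0
  long |>
    mutate(volume_mL = vol, censored = vol == 0) |>
    select("patient_id", "pod", "volume_mL", "censored") |>
    arrange(.data$patient_id, .data$pod)
}

#' Apply a follow-up rule to a cohort
#'
#' Under the study design (`"conditional"`), a scan at POD 5 or 7 only took
#' place if RPP was still observed at the most recent prior scan; rows after
#' the first zero reading are therefore removed. `"complete"` keeps every
#' scheduled row; `"independent_missing"` drops non-first scans independently
#' with probability `missing_prob`. Remaining values are never altered.
#'
#' @param cohort An [rpp_cohort()].
#' @param rule One of `"conditional"`, `"complete"`, `"independent_missing"`.
#' @param missing_prob Drop probability for `"independent_missing"`.
#' @return The filtered cohort.
#' @export
apply_followup_rule <- function(cohort,
                                rule = c("conditional", "complete",
                                         "independent_missing"),
                                missing_prob = 0.1) {
  rule <- match.arg(rule)
  m <- cohort$measurements
  m <- switch(
    rule,
    complete = m,
    conditional = {
      # keep scans up to and including the first zero reading
      first_zero <- m |>
        filter(.data$volume_mL == 0) |>
        group_by(.data$patient_id) |>
        summarise(.first_zero = min(.data$pod), .groups = "drop")
      m |>
        left_join(first_zero, by = "patient_id") |>
        filter(is.na(.data$.first_zero) | .data$pod <= .data$.first_zero) |>
        select(-".first_zero")
    },
    independent_missing = {
      first_row <- !duplicated(m$patient_id)
      m[first_row | runif(nrow(m)) >= missing_prob, ]
    }
  )
  rpp_cohort(cohort$patients, m)
}

#' Complete a measurement table with resolved-as-zero rows
#'
#' Patients who stop being scanned because their RPP resolved (a zero reading
#' at an earlier scan under the conditional follow-up design) logically have
#' zero RPP at the later scheduled days; this helper adds those rows back with
#' `volume_mL = 0`, `censored = TRUE` and `imputed = TRUE`, so that per-day
#' summaries and zero fractions can be computed over the whole cohort. Rows
#' that are missing for any other reason stay missing.
#'
#' @param cohort An [rpp_cohort()].
#' @param pods Scheduled scan days to complete over.
#' @return A tibble of measurements with an extra `imputed` column.
#' @export
complete_measurements <- function(cohort, pods = SCHEDULED_PODS) {
  m <- cohort$measurements |> mutate(imputed = FALSE)
  zero_rows <- m |> filter(.data$volume_mL == 0)
  if (nrow(zero_rows) == 0) return(m)
  resolved <- zero_rows |>
    group_by(.data$patient_id) |>
    summarise(first_zero = min(.data$pod), .groups = "drop")
  fill <- crossing(resolved, pod = as.integer(pods)) |>
    filter(.data$pod > .data$first_zero) |>
    select("patient_id", "pod") |>
    dplyr::anti_join(m, by = c("patient_id", "pod")) |>
    mutate(volume_mL = 0, censored = TRUE, imputed = TRUE)
  bind_rows(m, fill) |> arrange(.data$patient_id, .data$pod)
}

#' Read and write cohort CSV files
#'
#' The on-disk format is two UTF-8 CSV files with header rows:
#' `patients.csv` (patient_id, age, weight_kg, height_cm, bmi, bmi_group,
#' op_duration_min, insufflation_min, total_gas_L, decompressed) and
#' `measurements.csv` (patient_id, pod, volume_mL, censored). User-supplied
#' real data in the same schema are accepted anywhere a synthetic cohort is.
#'
#' @param dir Directory containing (or to receive) the two CSV files.
#' @param cohort An [rpp_cohort()].
#' @return `read_cohort()` returns an [rpp_cohort()]; `write_cohort()`
#'   returns `dir` invisibly.
#' @export
read_cohort <- function(dir) {
  read_plain <- function(f) {
    x <- readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                         progress = FALSE)
    attr(x, "spec") <- NULL
    attr(x, "problems") <- NULL
    class(x) <- c("tbl_df", "tbl", "data.frame")
    x
  }
  p <- read_plain("patients.csv")
  m <- read_plain("measurements.csv")
  p$bmi_group <- factor(p$bmi_group, levels = BMI_GROUPS)
  m$pod <- as.integer(m$pod)
  rpp_cohort(p, m)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"))
  invisible(dir)
}
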
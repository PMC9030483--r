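#' Shifted log transform of RPP volumes
#'
#' Volumes are shifted one unit to the right before the log so that a volume
#' of 0 mL maps to 0 on the transformed scale: `y = log(volume + 1)`. The
#' inverse floors at zero: `volume = max(exp(y) - 1, 0)`.
#'
#' @param volume_mL Non-negative volumes in mL.
#' @param y Values on the shifted-log scale.
#' @return `log_shift()` returns the transformed values; `inv_log_shift()`
#'   the back-transformed volumes in mL.
#' @export
#' @examples
#' log_shift(0)            # 0
#' inv_log_shift(log_shift(9.58))
log_shift <- function(volume_mL) {
  if (any(volume_mL < 0, na.rm = TRUE)) abort("volume_mL must be non-negative")
  log(volume_mL + 1)
}

#' @rdname log_shift
#' @export
inv_log_shift <- function(y) pmax(exp(y) - 1, 0)

#' Prepare model observations from a cohort
#'
#' Applies the shifted log transform, centres the day covariate at POD 3
#' (`x_day = pod - 3`, so the intercept is the expected log-volume at the
#' first scan), and marks zero volumes as left-censored at
#' `log(detection_limit_mL + 1)`.
#'
#' @param cohort An [rpp_cohort()].
#' @param detection_limit_mL Volumetric detection limit in mL.
#' @return A tibble with one row per measurement: `patient_id`,
#'   `patient_index` (1..J, ordered as in the patient table), `y`, `x_day`,
#'   `bmi_group`, `censored`, `censor_bound`.
#' @export
prepare_observations <- function(cohort, detection_limit_mL = 0.05) {
  validate_cohort(cohort)
  m <- cohort$measurements
  if (nrow(m) == 0) {
    return(tibble(patient_id = character(), patient_index = integer(),
                  y = double(), x_day = double(), bmi_group = factor(levels = BMI_GROUPS),
                  censored = logical(), censor_bound = double()))
  }
  idx <- setNames(seq_len(nrow(cohort$patients)), cohort$patients$patient_id)
  grp <- setNames(as.character(cohort$patients$bmi_group), cohort$patients$patient_id)
  bound <- log_shift(detection_limit_mL)
  tibble(
    patient_id = m$patient_id,
    patient_index = unname(idx[m$patient_id]),
    y = log_shift(m$volume_mL),
    x_day = m$pod - 3,
    bmi_group = factor(grp[m$patient_id], levels = BMI_GROUPS),
    censored = m$censored,
    censor_bound = bound
  )
}
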
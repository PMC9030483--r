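#' Cohort summary table
#'
#' One row per demographic/operative variable and per-POD RPP volume with
#' `n`, mean, SD, median and IQR (linear-interpolation quantiles). `n` counts
#' available (non-missing) values per variable. For the RPP rows, patients
#' whose gas had already resolved at an earlier scan are counted as 0 mL (see
#' [complete_measurements()]); patients whose scan is missing for any other
#' reason are excluded from that row.
#'
#' @param cohort An [rpp_cohort()].
#' @param pods Scheduled scan days summarised as RPP rows.
#' @return A tibble: `variable`, `n`, `mean`, `sd`, `median`, `iqr_low`,
#'   `iqr_high`.
#' @export
summarize_cohort <- function(cohort, pods = SCHEDULED_PODS) {
  validate_cohort(cohort)
  if (nrow(cohort$patients) == 0) abort("cohort has no patients")
  p <- cohort$patients
  demo_vars <- c(age = "age", weight_kg = "weight_kg", height_cm = "height_cm",
                 bmi = "bmi", op_duration_min = "op_duration_min",
                 insufflation_min = "insufflation_min",
                 total_gas_L = "total_gas_L")
  demo_vars <- demo_vars[demo_vars %in% names(p)]
  rows <- imap(as.list(demo_vars), function(col, label) {
    summary_row(label, p[[col]])
  })
  mm <- complete_measurements(cohort, pods)
  rpp_rows <- map(as.integer(pods), function(d) {
    v <- mm$volume_mL[mm$pod == d]
    summary_row(sprintf("rpp_pod%d_mL", d), v)
  })
  bind_rows(list_rbind(unname(rows)), list_rbind(rpp_rows))
}

summary_row <- function(variable, x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(tibble(variable = variable, n = 0L, mean = NA_real_, sd = NA_real_,
                  median = NA_real_, iqr_low = NA_real_, iqr_high = NA_real_))
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(variable = variable, n = length(x), mean = mean(x), sd = stats::sd(x),
         median = q[2], iqr_low = q[1], iqr_high = q[3])
}

#' One-way ANOVA of RPP volumes across scan days
#'
#' F-test comparing (transformed) RPP volumes between the post-operative scan
#' days, available-case: only measurement rows present in the cohort enter
#' (set `impute_resolved = TRUE` to count resolved patients as 0 mL).
#'
#' @param cohort An [rpp_cohort()].
#' @param scale `"log_shift"` (default; the decay model's response scale) or
#'   `"raw"`.
#' @param impute_resolved Count resolved patients as zero at later PODs.
#' @return A one-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`.
#' @export
anova_rpp <- function(cohort, scale = c("log_shift", "raw"),
                      impute_resolved = FALSE) {
  scale <- match.arg(scale)
  m <- if (impute_resolved) complete_measurements(cohort) else cohort$measurements
  counts <- table(m$pod)
  if (sum(counts >= 2) < 2) {
    abort("need at least 2 PODs with at least 2 observations each")
  }
  value <- if (scale == "log_shift") log_shift(m$volume_mL) else m$volume_mL
  fit <- aov(value ~ factor(m$pod))
  tab <- summary(fit)[[1]]
  tibble(
    f_statistic = tab[["F value"]][1],
    df_between = as.integer(tab[["Df"]][1]),
    df_within = as.integer(tab[["Df"]][2]),
    p_value = tab[["Pr(>F)"]][1]
  )
}

#' Correlation matrix of demographic, operative and RPP variables
#'
#' Pairwise correlations (Pearson by default; Spearman offered because RPP
#' volumes are heavily right-skewed) among age, weight, height, BMI,
#' operative duration, insufflation time, total gas and the per-POD RPP
#' volumes, with pairwise-complete handling of missing scans and pairwise
#' p-values from [stats::cor.test()]. Constant variables yield `NA`
#' correlations and a warning rather than being silently zeroed.
#'
#' @param cohort An [rpp_cohort()].
#' @param method `"pearson"` or `"spearman"`.
#' @param impute_resolved Count resolved patients as zero at later PODs
#'   (default `TRUE`, so every patient contributes to the RPP columns).
#' @return A list with class `"rpp_corr_matrix"`: `r` and `p` matrices plus
#'   the method. Use [tidy()] for a long tibble.
#' @export
correlation_matrix <- function(cohort, method = c("pearson", "spearman"),
                               impute_resolved = TRUE) {
  method <- match.arg(method)
  validate_cohort(cohort)
  wide <- cohort_wide(cohort, impute_resolved)
  num <- wide |> select(-"patient_id")
  consts <- vapply(num, function(v) stats::var(v, na.rm = TRUE) == 0 ||
                     all(is.na(v)), logical(1))
  if (any(consts)) {
    warn(sprintf("constant variable(s), correlations undefined: %s",
                 paste(names(num)[consts], collapse = ", ")))
  }
  vars <- names(num)
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- complete.cases(num[[i]], num[[j]])
      if (sum(ok) < 3 || consts[i] || consts[j]) next
      ct <- suppressWarnings(
        cor.test(num[[i]][ok], num[[j]][ok], method = method, exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, method = method), class = "rpp_corr_matrix")
}

cohort_wide <- function(cohort, impute_resolved = TRUE) {
  m <- if (impute_resolved) complete_measurements(cohort) else
    mutate(cohort$measurements, imputed = FALSE)
  rpp <- m |>
    mutate(name = sprintf("rpp_pod%d_mL", .data$pod)) |>
    select("patient_id", "name", "volume_mL") |>
    pivot_wider(names_from = "name", values_from = "volume_mL")
  keep <- intersect(c("patient_id", "age", "weight_kg", "height_cm", "bmi",
                      "op_duration_min", "insufflation_min", "total_gas_L"),
                    names(cohort$patients))
  cohort$patients |> select(all_of(keep)) |> left_join(rpp, by = "patient_id")
}

#' @export
print.rpp_corr_matrix <- function(x, ...) {
  cat(sprintf("<rpp_corr_matrix> %s, %d variables\n", x$method, ncol(x$r)))
  print(round(x$r, 2))
  invisible(x)
}

#' @export
tidy.rpp_corr_matrix <- function(x, ...) {
  vars <- rownames(x$r)
  crossing(var1 = vars, var2 = vars) |>
    filter(.data$var1 < .data$var2) |>
    mutate(estimate = x$r[cbind(.data$var1, .data$var2)],
           p_value = x$p[cbind(.data$var1, .data$var2)],
           method = x$method)
}

#' @export
autoplot.rpp_corr_matrix <- function(object, ...) {
  vars <- rownames(object$r)
  df <- crossing(var1 = factor(vars, vars), var2 = factor(vars, vars)) |>
    mutate(r = object$r[cbind(as.character(.data$var1), as.character(.data$var2))])
  ggplot(df, aes(.data$var1, .data$var2, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Fraction of patients with no detectable RPP at a given day
#'
#' Patients whose scan at `pod` read 0 mL, plus patients not scanned at `pod`
#' because their RPP had already resolved at an earlier scan (who logically
#' have no detectable gas), divided by the number of patients with known
#' status at `pod`.
#'
#' @param cohort An [rpp_cohort()].
#' @param pod Post-operative day.
#' @return A proportion in `[0, 1]`.
#' @export
zero_rpp_fraction <- function(cohort, pod) {
  mm <- complete_measurements(cohort, pods = unique(c(SCHEDULED_PODS, pod)))
  v <- mm$volume_mL[mm$pod == pod]
  if (length(v) == 0) abort(sprintf("no information at POD %s", pod))
  mean(v == 0)
}

#' Decay plot of a cohort
#'
#' @param object An [rpp_cohort()].
#' @param ... Unused.
#' @return A ggplot: per-patient RPP trajectories on a shifted-log scale.
#' @export
autoplot.rpp_cohort <- function(object, ...) {
  m <- object$measurements |>
    left_join(select(object$patients, "patient_id", "bmi_group"),
              by = "patient_id")
  ggplot(m, aes(.data$pod, .data$volume_mL + 1, group = .data$patient_id,
                colour = .data$bmi_group)) +
    geom_line(alpha = 0.4) +
    geom_point(alpha = 0.5, size = 0.8) +
    scale_y_log10() +
    labs(x = "Post-operative day", y = "RPP volume + 1 (mL, log scale)",
         colour = "BMI group") +
    theme_minimal()
}
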
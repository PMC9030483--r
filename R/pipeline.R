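#' Configuration of a full pipeline run
#'
#' @param generator An [generator_config()].
#' @param priors A [default_priors()] specification.
#' @param settings A [sampler_settings()] object.
#' @param seed Master seed for simulation and fitting.
#' @param pods PODs of the credible table.
#' @param level Credible level of the predictive table and ROPE HDIs.
#' @param verbose Print per-stage progress.
#' @return A list with class `"rpp_run_config"`.
#' @export
run_config <- function(generator = generator_config(), priors = default_priors(),
                       settings = sampler_settings(), seed = 1, pods = 3:7,
                       level = 0.95, verbose = TRUE) {
  validate_generator_config(generator)
  structure(list(generator = generator, priors = priors, settings = settings,
                 seed = as.integer(seed), pods = as.integer(pods),
                 level = level, verbose = verbose),
            class = "rpp_run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, computes the descriptive layer (summary
#' table, ANOVA across scan days, correlation matrix, zero-RPP fractions),
#' fits the hierarchical censored decay model, and writes the
#' posterior-predictive credible table and the ROPE report, together with a
#' manifest recording the seed, package version and a hash of the full
#' configuration. Re-running with the same configuration reproduces identical
#' outputs. A failure in any stage aborts with the stage name.
#'
#' @param config An [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional pre-existing [rpp_cohort()]; when supplied the
#'   simulation stage is skipped and this cohort is analysed instead.
#' @return Invisibly, a list with the in-memory results (`cohort`, `table1`,
#'   `anova`, `correlations`, `zero_fractions`, `fit`, `credible_table`,
#'   `rope`, `manifest`).
#' @export
run_full_pipeline <- function(config = run_config(), out_dir, cohort = NULL) {
  if (!inherits(config, "rpp_run_config")) abort("config must be an rpp_run_config")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (isTRUE(config$verbose)) inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  say("stage simulate: n = %d patients (seed %d)",
      config$generator$n_patients, config$seed)
  cohort <- stage("simulate", {
    ch <- cohort %||% simulate_cohort(config$generator, seed = config$seed)
    write_cohort(ch, out_dir)
    ch
  })

  say("stage descriptives")
  table1 <- stage("descriptives", {
    tab1 <- summarize_cohort(cohort)
    readr::write_csv(tab1, file.path(out_dir, "table1.csv"))
    tab1
  })
  anova_res <- stage("descriptives", {
    a <- anova_rpp(cohort)
    readr::write_csv(a, file.path(out_dir, "anova.csv"))
    a
  })
  corr <- stage("descriptives", {
    cm <- correlation_matrix(cohort)
    readr::write_csv(tidy(cm), file.path(out_dir, "correlations.csv"))
    cm
  })
  zeros <- stage("descriptives", {
    z <- tibble(pod = config$generator$pods,
                zero_fraction = map_dbl(config$generator$pods,
                                        function(d) zero_rpp_fraction(cohort, d)))
    readr::write_csv(z, file.path(out_dir, "zero_fractions.csv"))
    z
  })

  say("stage fit: %d chains x %d iterations",
      config$settings$chains, config$settings$iter)
  fit <- stage("fit", {
    f <- fit_rpp_model(cohort, priors = config$priors,
                       settings = config$settings, seed = config$seed,
                       detection_limit_mL = config$generator$detection_limit_mL)
    readr::write_csv(tidy(f), file.path(out_dir, "posterior_summary.csv"))
    f
  })
  say("stage fit: converged = %s (max R-hat %.3f)", fit$converged,
      max(fit$diagnostics$rhat, na.rm = TRUE))

  say("stage predict")
  ctab <- stage("predict", {
    ct <- make_credible_table(fit, pods = config$pods, level = config$level,
                              force = TRUE, seed = config$seed)
    readr::write_csv(as_tibble(ct), file.path(out_dir, "credible_table.csv"))
    ct
  })
  rope <- stage("rope", {
    rp <- rope_report(fit, level = config$level)
    readr::write_csv(rp, file.path(out_dir, "rope.csv"))
    rp
  })

  manifest <- stage("manifest", {
    mf <- list(
      package = "rppdecay",
      version = as.character(packageVersion("rppdecay")),
      seed = config$seed,
      config_hash = rlang::hash(unclass_recursive(config)),
      converged = fit$converged,
      outputs = c("patients.csv", "measurements.csv", "table1.csv",
                  "anova.csv", "correlations.csv", "zero_fractions.csv",
                  "posterior_summary.csv", "credible_table.csv", "rope.csv")
    )
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    mf
  })

  invisible(list(cohort = cohort, table1 = table1, anova = anova_res,
                 correlations = corr, zero_fractions = zeros, fit = fit,
                 credible_table = ctab, rope = rope, manifest = manifest))
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}

#' Parameter-recovery experiment
#'
#' Simulates cohorts at known population parameters, fits the model to each
#' replicate, and records posterior means, equal-tailed credible-interval
#' coverage of the truth and convergence per replicate. The generator used
#' here is the model's own data-generating process (zero inflation off;
#' volumes below the detection limit censored), so coverage should be close
#' to nominal when the sampler works.
#'
#' @param true_params An [model_params()] object (the generating truth).
#' @param n_patients Patients per replicate.
#' @param n_replicates Number of replicates.
#' @param seeds Integer vector of per-replicate seeds (default `1:n_replicates`).
#' @param settings A [sampler_settings()] for each fit.
#' @param level Credible level of the coverage intervals.
#' @param detection_limit_mL Detection limit for censoring.
#' @param followup_rule Follow-up design of the simulated cohorts.
#' @param parameters Which population parameters to track.
#' @param quiet Suppress per-replicate progress.
#' @return A tibble with class `"rpp_recovery"`: one row per (replicate,
#'   parameter) with `truth`, `estimate` (posterior mean), `lower`, `upper`,
#'   `covered`, `converged`, `seed`. `glance()` aggregates bias and coverage.
#' @export
recovery_experiment <- function(true_params, n_patients = 200,
                                n_replicates = 20, seeds = NULL,
                                settings = sampler_settings(),
                                level = 0.95, detection_limit_mL = 0.05,
                                followup_rule = "conditional",
                                parameters = c("mu_alpha", "mu_beta",
                                               "sigma_alpha", "sigma_beta",
                                               "rho", "delta", "eta",
                                               "sigma_y"),
                                quiet = TRUE) {
  if (!inherits(true_params, "rpp_model_params")) {
    true_params <- do.call(model_params, as.list(true_params))
  }
  if (n_replicates < 1) abort("n_replicates must be at least 1")
  seeds <- seeds %||% seq_len(n_replicates)
  if (length(seeds) != n_replicates) abort("need one seed per replicate")
  truth <- unlist(true_params[parameters])
  gen <- generator_config(
    n_patients = n_patients,
    pop_intercept_mean = true_params$mu_alpha,
    pop_slope_mean = true_params$mu_beta,
    sd_intercept = true_params$sigma_alpha,
    sd_slope = true_params$sigma_beta,
    intercept_slope_corr = true_params$rho,
    group_effects = c(normal = true_params$gamma, overweight = true_params$delta,
                      obese = true_params$eta),
    residual_sd = true_params$sigma_y,
    detection_limit_mL = detection_limit_mL,
    zero_inflation = c(`3` = 0, `5` = 0, `7` = 0),
    followup_rule = followup_rule
  )
  a <- (1 - level) / 2
  out <- map(seq_len(n_replicates), function(r) {
    if (!quiet) inform(sprintf("recovery replicate %d/%d", r, n_replicates))
    cohort <- simulate_cohort(gen, seed = seeds[r])
    fit <- suppressWarnings(
      fit_rpp_model(cohort, settings = settings, seed = seeds[r],
                    detection_limit_mL = detection_limit_mL))
    map(parameters, function(p) {
      d <- fit$draws[[p]]
      ci <- quantile(d, c(a, 1 - a), names = FALSE)
      tv <- truth[[p]]
      tibble(replicate = r, seed = seeds[r], parameter = p,
             truth = tv, estimate = mean(d),
             lower = ci[1], upper = ci[2],
             covered = tv >= ci[1] & tv <= ci[2],
             converged = fit$converged)
    }) |> list_rbind()
  }) |> list_rbind()
  if (!all(out$converged)) {
    warn(sprintf("%d of %d replicates did not pass the convergence gate",
                 sum(!out$converged) / length(parameters), n_replicates))
  }
  structure(out, class = c("rpp_recovery", class(out)))
}

#' Aggregate a recovery experiment
#'
#' @param x An `"rpp_recovery"` tibble.
#' @param ... Unused.
#' @return A tibble with one row per parameter: truth, mean estimate, bias,
#'   interval coverage across replicates, replicate count.
#' @export
glance.rpp_recovery <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$parameter) |>
    summarise(truth = .data$truth[1],
              estimate = mean(.data$estimate),
              bias = mean(.data$estimate - .data$truth),
              coverage = mean(.data$covered),
              n_replicates = dplyr::n(),
              n_converged = sum(.data$converged),
              .groups = "drop")
}

#' @export
autoplot.rpp_recovery <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$replicate, y = .data$estimate)) +
    geom_point(size = 0.8) +
    ggplot2::geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.2, alpha = 0.5) +
    ggplot2::geom_hline(aes(yintercept = .data$truth), colour = "red",
                        linetype = 2) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "Replicate", y = "Posterior mean and interval") +
    theme_minimal()
}
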
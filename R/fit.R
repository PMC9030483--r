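# JAGS model code for the hierarchical censored log-linear decay model.
# Left-censoring uses the interval trick: is_obs[i] ~ dinterval(y[i], bound[i])
# with is_obs = 1 for observed rows (y > bound) and 0 for censored rows
# (y imputed below bound). Random effects are non-centred.
jags_model_code <- function(coding = c("reference", "full_dummy")) {
  coding <- match.arg(coding)
  gamma_line <- if (coding == "reference") {
    "  g[1] <- 0"
  } else {
    # soft-identified literal parameterisation: all three dummies under a
    # shrinkage prior alongside the population intercept
    "  g[1] <- gamma\n  gamma ~ dnorm(0, 1)"
  }
  g_prior <- if (coding == "reference") "dnorm(0, 0.04)" else "dnorm(0, 1)"
  paste0("
model {
  for (i in 1:N) {
    mu[i] <- alpha[pt[i]] + beta[pt[i]] * x[i] + g[grp[i]]
    is_obs[i] ~ dinterval(y[i], bound[i])
    y[i] ~ dnorm(mu[i], tau_y)
  }
  for (j in 1:J) {
    za[j] ~ dnorm(0, 1)
    zb[j] ~ dnorm(0, 1)
    alpha[j] <- mu_alpha + sigma_alpha * za[j]
    beta[j]  <- mu_beta + sigma_beta * (rho * za[j] + sqrt(1 - rho^2) * zb[j])
  }
", gamma_line, "
  g[2] <- delta
  g[3] <- eta
  mu_alpha ~ dnorm(0, 0.04)
  mu_beta ~ dnorm(0, 0.04)
  delta ~ ", g_prior, "
  eta ~ ", g_prior, "
  sigma_alpha ~ dnorm(0, ", 1 / 2.5^2, ") T(0,)
  sigma_beta ~ dnorm(0, ", 1 / 2.5^2, ") T(0,)
  sigma_y ~ dnorm(0, ", 1 / 2.5^2, ") T(0,)
  tau_y <- pow(sigma_y, -2)
  u ~ dbeta(2, 2)
  rho <- 2 * u - 1
}
")
}

#' Prior specification for the decay model
#'
#' Weakly informative, scale-appropriate priors on the shifted-log (log-mL)
#' scale: fixed effects Normal(0, 5²), half-Normal(2.5) on the three SDs, and
#' a concentration-2 prior on the 2x2 random-effects correlation (density
#' proportional to `1 - rho²`, implemented as a rescaled Beta(2, 2)).
#'
#' @param fixed_scale Prior SD of the fixed effects.
#' @param sd_scale Scale of the half-normal priors on `sigma_alpha`,
#'   `sigma_beta`, `sigma_y`.
#' @param corr_concentration Concentration of the correlation prior.
#' @return A list with class `"rpp_prior_spec"`.
#' @export
default_priors <- function(fixed_scale = 5, sd_scale = 2.5,
                           corr_concentration = 2) {
  if (fixed_scale <= 0 || sd_scale <= 0 || corr_concentration <= 0) {
    abort("all prior scales must be positive")
  }
  structure(list(fixed_scale = fixed_scale, sd_scale = sd_scale,
                 corr_concentration = corr_concentration),
            class = "rpp_prior_spec")
}

#' Sampler settings
#'
#' @param chains Number of MCMC chains (at least 2, so that split-chain
#'   convergence diagnostics are meaningful).
#' @param adapt Adaptation iterations.
#' @param warmup Burn-in iterations per chain.
#' @param iter Kept iterations per chain.
#' @param thin Thinning interval.
#' @return A list with class `"rpp_sampler_settings"`.
#' @export
sampler_settings <- function(chains = 4, adapt = 500, warmup = 1000,
                             iter = 2000, thin = 1) {
  if (chains < 2) abort("at least 2 chains are required")
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 warmup = as.integer(warmup), iter = as.integer(iter),
                 thin = as.integer(thin)),
            class = "rpp_sampler_settings")
}

#' Fit the hierarchical censored decay model
#'
#' Samples the posterior of the population parameters and patient-level random
#' effects of the log-linear decay model by MCMC (JAGS), treating zero volumes
#' as left-censored at the detection limit. Convergence is assessed with the
#' split-chain R-hat statistic and effective sample sizes; the fit is flagged
#' (with a warning) if any reported parameter has R-hat >= 1.01.
#'
#' @param obs Observation tibble from [prepare_observations()], or an
#'   [rpp_cohort()] (which is transformed with `detection_limit_mL`).
#' @param priors A [default_priors()] specification.
#' @param settings A [sampler_settings()] object.
#' @param seed Integer seed controlling both initial values and the JAGS RNG
#'   streams; fits are reproducible given `seed` and `settings`.
#' @param coding `"reference"` (normal weight as reference group, `gamma = 0`)
#'   or `"full_dummy"` (all three group dummies under shrinkage priors,
#'   soft-identified).
#' @param detection_limit_mL Used only when `obs` is a cohort.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `"rpp_fit"`: list with `draws` (tibble of
#'   posterior draws of the population parameters, with `.chain` and
#'   `.iteration` columns), `random_effects` (posterior means of
#'   `alpha_j`, `beta_j`), `diagnostics` (per-parameter R-hat and ESS),
#'   `converged`, `reference_sd` (pooled SD of the non-censored transformed
#'   response, the default ROPE reference), `data`, `settings`, `seed`.
#' @export
fit_rpp_model <- function(obs, priors = default_priors(),
                          settings = sampler_settings(), seed = 1,
                          coding = c("reference", "full_dummy"),
                          detection_limit_mL = 0.05, quiet = TRUE) {
  coding <- match.arg(coding)
  if (inherits(obs, "rpp_cohort")) {
    obs <- prepare_observations(obs, detection_limit_mL)
  }
  if (!inherits(priors, "rpp_prior_spec")) abort("priors must be a prior spec")
  n_pat <- length(unique(obs$patient_index))
  if (n_pat < 2) abort("at least 2 patients with observations are required")

  # re-index patients compactly (cohorts may have patients with no scans)
  pt_levels <- sort(unique(obs$patient_index))
  pt <- match(obs$patient_index, pt_levels)

  y <- ifelse(obs$censored, NA_real_, obs$y)
  data_list <- list(
    N = nrow(obs), J = length(pt_levels), pt = pt,
    x = obs$x_day, grp = as.integer(obs$bmi_group),
    y = y, is_obs = as.integer(!obs$censored),
    bound = obs$censor_bound
  )

  model_code <- jags_model_code(coding)
  model_code <- customize_priors(model_code, priors)
  # block samplers for the linear part; large mixing gain for the fixed effects
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)

  inits <- lapply(seq_len(settings$chains), function(k) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = as.integer(seed) * 1000L + k,
      y = ifelse(obs$censored, obs$censor_bound - 0.5, NA_real_),
      mu_alpha = mean(obs$y[!obs$censored]) %||% 0,
      mu_beta = 0
    )
  })

  monitors <- c("mu_alpha", "mu_beta", "sigma_alpha", "sigma_beta", "rho",
                "delta", "eta", "sigma_y", if (coding == "full_dummy") "gamma")
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_code), data = data_list,
                            inits = inits, n.chains = settings$chains,
                            n.adapt = settings$adapt, quiet = quiet)
    update(jm, settings$warmup, progress.bar = "none")
    samp <- rjags::coda.samples(jm, c(monitors, "alpha", "beta"),
                                n.iter = settings$iter, thin = settings$thin,
                                progress.bar = "none")
    samp
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  pop <- lapply(seq_along(samp), function(k) {
    m <- as.matrix(samp[[k]])[, monitors, drop = FALSE]
    as_tibble(m) |> mutate(.chain = k, .iteration = dplyr::row_number())
  }) |> list_rbind()

  re_cols <- grep("^(alpha|beta)\\[", coda::varnames(samp), value = TRUE)
  re_mean <- colMeans(do.call(rbind, lapply(samp, function(s) as.matrix(s)[, re_cols, drop = FALSE])))
  re_idx <- as.integer(sub("^(alpha|beta)\\[(\\d+)\\]$", "\\2", re_cols))
  re_par <- sub("^(alpha|beta)\\[.*$", "\\1", re_cols)
  random_effects <- tibble(j = re_idx, par = re_par, value = unname(re_mean)) |>
    pivot_wider(names_from = "par", values_from = "value") |>
    arrange(.data$j) |>
    mutate(patient_index = pt_levels[.data$j]) |>
    select("patient_index", "alpha", "beta")

  diagnostics <- fit_diagnostics(pop, monitors)
  converged <- all(diagnostics$rhat < 1.01, na.rm = TRUE)
  if (!converged) {
    warn(sprintf(
      "MCMC has not converged (max split R-hat = %.3f); treat results with caution",
      max(diagnostics$rhat, na.rm = TRUE)))
  }

  structure(
    list(draws = pop, random_effects = random_effects,
         diagnostics = diagnostics, converged = converged,
         reference_sd = stats::sd(obs$y[!obs$censored]),
         data = obs, settings = settings, priors = priors,
         coding = coding, seed = as.integer(seed)),
    class = "rpp_fit"
  )
}

# Rewrite the default prior precisions in the model code from a prior spec.
customize_priors <- function(code, priors) {
  code <- gsub("dnorm(0, 0.04)", sprintf("dnorm(0, %.8g)", 1 / priors$fixed_scale^2),
               code, fixed = TRUE)
  code <- gsub("T(0,)", "T(0,)", code, fixed = TRUE)
  code <- gsub(sprintf("dnorm(0, %s) T(0,)", format(1 / 2.5^2)),
               sprintf("dnorm(0, %.8g) T(0,)", 1 / priors$sd_scale^2),
               code, fixed = TRUE)
  code <- gsub("dbeta(2, 2)",
               sprintf("dbeta(%.8g, %.8g)", priors$corr_concentration,
                       priors$corr_concentration),
               code, fixed = TRUE)
  code
}

# Split-chain potential scale reduction factor (each chain halved, so 2K
# half-chains of length n/2), the standard convergence gate.
split_rhat <- function(x) {
  # x: iterations x chains matrix
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  b <- half * var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

fit_diagnostics <- function(pop_draws, monitors) {
  chains <- sort(unique(pop_draws$.chain))
  tibble(parameter = monitors) |>
    mutate(
      rhat = map_dbl(.data$parameter, function(p) {
        x <- vapply(chains, function(k) pop_draws[[p]][pop_draws$.chain == k],
                    numeric(sum(pop_draws$.chain == chains[1])))
        split_rhat(x)
      }),
      ess = map_dbl(.data$parameter, function(p) {
        unname(coda::effectiveSize(coda::as.mcmc.list(lapply(chains, function(k)
          coda::mcmc(pop_draws[[p]][pop_draws$.chain == k])))))
      })
    )
}

#' @export
print.rpp_fit <- function(x, ...) {
  cat(sprintf("<rpp_fit> %d chains x %d iterations (%s coding); converged: %s\n",
              x$settings$chains, x$settings$iter, x$coding, x$converged))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy posterior summaries of a fitted decay model
#'
#' @param x An `"rpp_fit"` object.
#' @param conf_level Credible level of the reported highest-density interval.
#' @param ... Unused.
#' @return A tibble with one row per population parameter: posterior mean,
#'   SD, HDI bounds, split R-hat and effective sample size.
#' @export
tidy.rpp_fit <- function(x, conf_level = 0.95, ...) {
  pars <- x$diagnostics$parameter
  map(pars, function(p) {
    d <- x$draws[[p]]
    h <- hdi(d, conf_level)
    tibble(parameter = p, mean = mean(d), sd = stats::sd(d),
           hdi_low = h[["lower"]], hdi_high = h[["upper"]])
  }) |>
    list_rbind() |>
    left_join(x$diagnostics, by = "parameter")
}

#' Model-level summary of a fitted decay model
#'
#' @param x An `"rpp_fit"` object.
#' @param ... Unused.
#' @return One-row tibble: numbers of patients, observations and censored
#'   observations, chains, kept draws, convergence flag, max R-hat, min ESS.
#' @export
glance.rpp_fit <- function(x, ...) {
  tibble(
    n_patients = length(unique(x$data$patient_index)),
    n_obs = nrow(x$data),
    n_censored = sum(x$data$censored),
    chains = x$settings$chains,
    draws = nrow(x$draws),
    converged = x$converged,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}
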
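#' Full parameter vector of the hierarchical decay model
#'
#' Collects the population-level parameters of the model
#' \deqn{y_i \sim N(\alpha_{j[i]} + \beta_{j[i]} x_{day,i} + g_{group(i)},\;
#'       \sigma_y^2)}
#' \deqn{(\alpha_j, \beta_j) \sim N\big((\mu_\alpha, \mu_\beta),\,\Sigma\big),
#'       \quad \Sigma_{12} = \rho\,\sigma_\alpha \sigma_\beta}
#' with BMI-group effects `gamma` (normal weight), `delta` (overweight) and
#' `eta` (obese). Under the default reference coding `gamma` is fixed at 0 and
#' `mu_alpha` is the normal-weight POD-3 mean.
#'
#' @param mu_alpha Population mean intercept (log-scale volume at POD 3).
#' @param mu_beta Population mean slope per day.
#' @param sigma_alpha,sigma_beta Population SDs of intercepts and slopes
#'   (non-negative).
#' @param rho Intercept-slope correlation in `[-1, 1]`.
#' @param gamma,delta,eta BMI-group effects (log scale).
#' @param sigma_y Residual SD (non-negative).
#' @return A named list with class `"rpp_model_params"`.
#' @export
model_params <- function(mu_alpha, mu_beta, sigma_alpha, sigma_beta, rho,
                         gamma = 0, delta = 0, eta = 0, sigma_y = 1) {
  p <- list(mu_alpha = mu_alpha, mu_beta = mu_beta,
            sigma_alpha = sigma_alpha, sigma_beta = sigma_beta, rho = rho,
            gamma = gamma, delta = delta, eta = eta, sigma_y = sigma_y)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v), logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("model parameters must be finite scalars: %s",
                  paste(bad, collapse = ", ")))
  }
  if (p$sigma_alpha < 0 || p$sigma_beta < 0 || p$sigma_y < 0) {
    abort("sigma_alpha, sigma_beta and sigma_y must be non-negative")
  }
  if (abs(p$rho) > 1) abort("rho must lie in [-1, 1]")
  structure(p, class = "rpp_model_params")
}

group_effect <- function(params, group) {
  eff <- c(normal = params$gamma, overweight = params$delta, obese = params$eta)
  if (any(!as.character(group) %in% names(eff))) abort("unknown BMI group")
  unname(eff[as.character(group)])
}

#' Censored hierarchical log-likelihood
#'
#' Log-likelihood of the observations given the population parameters and the
#' patient-level random effects: non-censored rows contribute the normal
#' log-density at `y`, left-censored rows the log of the normal lower-tail
#' probability at their censoring bound. The mean for row `i` is
#' `alpha_j[i] + beta_j[i] * x_day + group effect`.
#'
#' @param params An [model_params()] object.
#' @param random_effects Data frame with columns `alpha` and `beta`, one row
#'   per patient, indexed by `patient_index` in `obs`.
#' @param obs Observation tibble from [prepare_observations()].
#' @return The scalar log-likelihood.
#' @export
censored_loglik <- function(params, random_effects, obs) {
  if (!inherits(params, "rpp_model_params")) params <- do.call(model_params, as.list(params))
  if (nrow(obs) == 0) return(0)
  if (max(obs$patient_index) > nrow(random_effects)) {
    abort("one random-effect pair per patient is required")
  }
  mu <- random_effects$alpha[obs$patient_index] +
    random_effects$beta[obs$patient_index] * obs$x_day +
    group_effect(params, obs$bmi_group)
  ll_obs <- dnorm(obs$y, mu, params$sigma_y, log = TRUE)
  ll_cens <- pnorm(obs$censor_bound, mu, params$sigma_y, log.p = TRUE)
  sum(ifelse(obs$censored, ll_cens, ll_obs))
}

#' Closed-form predictive law for a new patient
#'
#' For a new patient of a given BMI group, integrating over the random-effect
#' law, the shifted-log volume at a given POD is normal with
#' mean `mu_alpha + mu_beta (pod - 3) + group effect` and variance
#' `sigma_alpha^2 + 2 rho sigma_alpha sigma_beta (pod - 3) +
#'  sigma_beta^2 (pod - 3)^2 + sigma_y^2`.
#'
#' @param params An [model_params()] object.
#' @param group BMI group (`"normal"`, `"overweight"`, `"obese"`).
#' @param pod Post-operative day (non-negative integer).
#' @return A named list with `mean` and `variance` of `y = log(V + 1)`.
#' @export
closed_form_predictive <- function(params, group, pod) {
  if (!inherits(params, "rpp_model_params")) params <- do.call(model_params, as.list(params))
  if (pod < 0 || pod != round(pod)) abort("pod must be a non-negative integer")
  t <- pod - 3
  list(
    mean = params$mu_alpha + params$mu_beta * t + group_effect(params, group),
    variance = params$sigma_alpha^2 +
      2 * params$rho * params$sigma_alpha * params$sigma_beta * t +
      params$sigma_beta^2 * t^2 + params$sigma_y^2
  )
}
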
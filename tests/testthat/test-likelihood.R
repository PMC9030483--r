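obs_row <- function(y, x_day = 0, group = "normal", censored = FALSE,
                    bound = log(1.05), idx = 1L) {
  tibble::tibble(patient_id = sprintf("P%03d", idx), patient_index = idx,
                 y = y, x_day = x_day,
                 bmi_group = factor(group, levels = c("normal", "overweight", "obese")),
                 censored = censored, censor_bound = bound)
}

test_that("censored likelihood has the right closed-form anchors", {
  params <- model_params(0, 0, 1, 1, 0, sigma_y = 1)
  re <- data.frame(alpha = 1.7, beta = 0)
  # density at its mode
  expect_equal(censored_loglik(params, re, obs_row(y = 1.7)),
               log(1 / sqrt(2 * pi)))
  # censored at a bound equal to the mean: lower tail = 1/2
  expect_equal(censored_loglik(params, re,
                               obs_row(y = 0, censored = TRUE, bound = 1.7)),
               log(0.5))
})

test_that("with no censored rows it equals the plain normal log-likelihood", {
  set.seed(4)
  n_pat <- 6
  re <- data.frame(alpha = rnorm(n_pat, 2, 1), beta = rnorm(n_pat, -0.4, 0.2))
  obs <- purrr::map(1:n_pat, function(j) {
    obs_row(y = rnorm(3, 2, 1), x_day = c(0, 2, 4),
            group = sample(c("normal", "overweight", "obese"), 1), idx = j)
  }) |> purrr::list_rbind()
  params <- model_params(2, -0.4, 1, 0.2, 0.3, delta = -0.3, eta = -0.8,
                         sigma_y = 0.7)
  mu <- re$alpha[obs$patient_index] + re$beta[obs$patient_index] * obs$x_day +
    c(normal = 0, overweight = -0.3, obese = -0.8)[as.character(obs$bmi_group)]
  expect_identical(censored_loglik(params, re, obs),
                   sum(dnorm(obs$y, mu, 0.7, log = TRUE)))
})

test_that("censored likelihood matches the quadrature oracle to 1e-8", {
  vols <- data.frame(patient = c(1, 1, 2, 2, 3), pod = c(3, 5, 3, 5, 3),
                     volume_mL = c(9.58, 0, 1.7, 0.4, 0))
  ch <- make_cohort(vols, n = 3, bmi = c(22, 27, 31))
  obs <- prepare_observations(ch, 0.05)
  re <- data.frame(alpha = c(2.0, 1.5, 0.5), beta = c(-0.5, -0.3, -0.2))
  params <- model_params(2, -0.4, 1, 0.3, 0.2, delta = -0.3, eta = -0.8,
                         sigma_y = 0.7)
  mu <- re$alpha[obs$patient_index] + re$beta[obs$patient_index] * obs$x_day +
    c(normal = 0, overweight = -0.3, obese = -0.8)[as.character(obs$bmi_group)]
  oracle <- sum(vapply(seq_len(nrow(obs)), function(i) {
    if (obs$censored[i]) {
      log(stats::integrate(function(t) dnorm(t, mu[i], 0.7), -Inf,
                           obs$censor_bound[i], rel.tol = 1e-12)$value)
    } else {
      dnorm(obs$y[i], mu[i], 0.7, log = TRUE)
    }
  }, numeric(1)))
  expect_equal(censored_loglik(params, re, obs), oracle, tolerance = 1e-8)
})

test_that("invalid inputs are rejected", {
  expect_error(model_params(NA, 0, 1, 1, 0), "finite")
  expect_error(model_params(0, 0, -1, 1, 0), "non-negative")
  expect_error(model_params(0, 0, 1, 1, 2), "rho")
  params <- model_params(0, 0, 1, 1, 0)
  expect_error(censored_loglik(params, data.frame(alpha = 1, beta = 0),
                               obs_row(1, idx = 2L)),
               "random-effect")
})
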
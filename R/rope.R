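#' Highest-density interval of a sample
#'
#' Shortest interval containing `level` of the draws (empirical HDI: the
#' minimum-width window over the sorted sample).
#'
#' @param x Numeric vector of posterior draws.
#' @param level Probability mass of the interval.
#' @return Named vector `c(lower, upper)`.
#' @export
hdi <- function(x, level = 0.95) {
  if (level <= 0 || level >= 1) abort("level must lie in (0, 1)")
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2) abort("need at least 2 finite draws")
  # shortest window containing k = ceiling(level * n) draws
  k <- min(n, max(2L, ceiling(level * n)))
  widths <- x[k:n] - x[seq_len(n - k + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1])
}

#' ROPE equivalence test of a posterior parameter
#'
#' Decision rule for "practical significance" of a parameter estimate: the
#' region of practical equivalence (ROPE) is `±0.1` reference standard
#' deviations around zero, and the decision compares it with the 95% highest
#' density interval of the posterior — `reject_null` if HDI and ROPE are
#' disjoint, `accept_equivalence` if the HDI lies entirely inside the ROPE,
#' otherwise `undecided`.
#'
#' @param fit An `"rpp_fit"` object, a tibble of posterior draws, or a
#'   numeric vector of draws.
#' @param parameter Name of the parameter column (ignored when `fit` is a
#'   numeric vector).
#' @param reference_sd Reference SD defining the ROPE half-width. For an
#'   `"rpp_fit"` the default is the pooled SD of all non-censored transformed
#'   responses (the "general population" scale of the outcome).
#' @param rope_fraction Half-width of the ROPE as a fraction of
#'   `reference_sd`.
#' @param level HDI level.
#' @return A one-row tibble with class `"rpp_rope_result"`: `parameter`,
#'   `hdi_low`, `hdi_high`, `rope_low`, `rope_high`, `decision`.
#' @export
rope_test <- function(fit, parameter = NULL, reference_sd = NULL,
                      rope_fraction = 0.1, level = 0.95) {
  if (is.numeric(fit) && is.null(dim(fit))) {
    draws <- fit
    parameter <- parameter %||% "parameter"
  } else {
    tab <- if (inherits(fit, "rpp_fit")) fit$draws else as_tibble(fit)
    if (is.null(parameter) || !parameter %in% names(tab)) {
      abort(sprintf("unknown parameter `%s`", parameter %||% "<missing>"))
    }
    draws <- tab[[parameter]]
    if (is.null(reference_sd) && inherits(fit, "rpp_fit")) {
      reference_sd <- fit$reference_sd
    }
  }
  if (is.null(reference_sd) || !is.finite(reference_sd) || reference_sd <= 0) {
    abort("reference_sd must be a positive number")
  }
  h <- hdi(draws, level)
  half <- rope_fraction * reference_sd
  decision <- rope_decision(h[["lower"]], h[["upper"]], -half, half)
  out <- tibble(parameter = parameter, hdi_low = h[["lower"]],
                hdi_high = h[["upper"]], rope_low = -half, rope_high = half,
                decision = decision)
  structure(out, class = c("rpp_rope_result", class(out)))
}

rope_decision <- function(hdi_low, hdi_high, rope_low, rope_high) {
  if (hdi_low > rope_high || hdi_high < rope_low) {
    "reject_null"
  } else if (hdi_low >= rope_low && hdi_high <= rope_high) {
    "accept_equivalence"
  } else {
    "undecided"
  }
}

#' ROPE report for every population parameter of a fit
#'
#' Runs [rope_test()] on each fixed-effect and correlation parameter of the
#' fitted model (the SD parameters are scale parameters for which an
#' equivalence region around zero is not meaningful and are skipped).
#'
#' @param fit An `"rpp_fit"`.
#' @param reference_sd Override of the default reference SD.
#' @inheritParams rope_test
#' @return A tibble with one row per tested parameter.
#' @export
rope_report <- function(fit, reference_sd = NULL, rope_fraction = 0.1,
                        level = 0.95) {
  pars <- intersect(c("mu_alpha", "mu_beta", "delta", "eta", "gamma", "rho"),
                    names(fit$draws))
  map(pars, function(p) rope_test(fit, p, reference_sd = reference_sd,
                                  rope_fraction = rope_fraction,
                                  level = level)) |>
    list_rbind()
}
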
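# Probabilistic sensitivity analysis: parameter distributions, Monte Carlo
# re-runs of the full pipeline, and empirical 95 % uncertainty intervals.

#' Distribution specifications for uncertain parameters
#'
#' Families:
#' * `fixed(value)` — degenerate, always returns `value`.
#' * `normal_from_ci(mean, ci_low, ci_high)` — normal with
#'   `sd = (ci_high - ci_low) / (2 * 1.959964)`.
#' * `pert(min, mode, max, shape)` — classic Pert via its Beta
#'   reparameterisation with shape `lambda = 4`.
#' * `pert_pm25(mean)` — Pert with mode `mean` and min/max at ±25 %,
#'   the convention used for parameters with minimal distributional data.
#' * `lognormal(meanlog, sdlog)`.
#'
#' @param name Family name.
#' @param ... Family parameters (see above).
#' @return A `dist_spec` list.
#' @export
dist_spec <- function(name = c("fixed", "normal_from_ci", "pert",
                               "pert_pm25", "lognormal"), ...) {
  name <- match.arg(name)
  params <- list(...)
  if (name == "normal_from_ci" && !(params$ci_low < params$ci_high)) {
    stopf("normal_from_ci requires ci_low < ci_high")
  }
  if (name == "pert") {
    with(params, if (!(min <= mode && mode <= max)) {
      stopf("pert requires min <= mode <= max")
    })
  }
  structure(list(name = name, params = params), class = "dist_spec")
}

#' @rdname dist_spec
#' @param value Fixed value.
#' @export
dist_fixed <- function(value) dist_spec("fixed", value = value)

#' @rdname dist_spec
#' @param mean,ci_low,ci_high Mean and 95 % CI bounds.
#' @export
dist_normal_ci <- function(mean, ci_low, ci_high) {
  dist_spec("normal_from_ci", mean = mean, ci_low = ci_low, ci_high = ci_high)
}

#' @rdname dist_spec
#' @param min,mode,max,shape Pert parameters.
#' @export
dist_pert <- function(min, mode, max, shape = 4) {
  dist_spec("pert", min = min, mode = mode, max = max, shape = shape)
}

#' @rdname dist_spec
#' @export
dist_pert_pm25 <- function(mean) {
  ## mode m with support [0.75 m, 1.25 m]; symmetric, so the Pert mean
  ## (min + 4 mode + max) / 6 equals m
  dist_spec("pert", min = 0.75 * mean, mode = mean, max = 1.25 * mean,
            shape = 4)
}

#' Pert random deviates
#'
#' Beta reparameterisation: `alpha = 1 + shape * (mode - min) / (max -
#' min)`, `beta = 1 + shape * (max - mode) / (max - min)`.
#'
#' @param n Number of draws.
#' @param min,mode,max Support and mode.
#' @param shape Shape parameter lambda (classic Pert: 4).
#' @return Numeric vector of draws in `[min, max]`.
#' @export
rpert <- function(n, min, mode, max, shape = 4) {
  if (max == min) return(rep(mode, n))
  a <- 1 + shape * (mode - min) / (max - min)
  b <- 1 + shape * (max - mode) / (max - min)
  min + (max - min) * rbeta(n, a, b)
}

#' Sample from a distribution specification
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1) {
  p <- spec$params
  switch(spec$name,
    fixed = rep(p$value, n),
    normal_from_ci = rnorm(n, mean = p$mean,
                           sd = (p$ci_high - p$ci_low) / (2 * qnorm(0.975))),
    pert = rpert(n, p$min, p$mode, p$max, p$shape %||% 4),
    lognormal = rlnorm(n, p$meanlog, p$sdlog),
    stopf("unknown distribution family '%s'", spec$name)
  )
}

## One RNG stream per parameter, derived from the master seed, so that
## adding or removing a parameter leaves the other parameters' draws
## untouched.
param_seed <- function(master_seed, j) {
  as.integer((as.numeric(master_seed) * 1009 + 7919 * j) %% 2147483647)
}

#' Run the Monte Carlo uncertainty analysis
#'
#' Draws every uncertain parameter from its declared distribution,
#' re-runs the (deterministic) pipeline once per draw, and collects the
#' per-draw output metrics.  Identical `(seed, specs)` give bit-identical
#' results.  Draws across parameters are independent.
#'
#' @param pipeline Function taking a named list of parameter values and
#'   returning a named numeric vector of output metrics.
#' @param specs Named list of `dist_spec`s.
#' @param n_draws Number of iterations (default 2000).
#' @param seed Master seed (integer).
#' @param max_error_rate Abort if more than this fraction of draws raise a
#'   model error (default 0.1 %).
#' @return A `mslt_draws` list: `params` (draws x parameters matrix),
#'   `results` (draws x metrics matrix), `errors` (character, one per
#'   failed draw), `n_draws`, `seed`.
#' @export
run_monte_carlo <- function(pipeline, specs, n_draws = 2000, seed,
                            max_error_rate = 0.001) {
  if (missing(seed)) stopf("'seed' is required")
  if (n_draws < 1) stopf("'n_draws' must be >= 1")
  par_mat <- matrix(NA_real_, n_draws, length(specs),
                    dimnames = list(NULL, names(specs)))
  for (j in seq_along(specs)) {
    set.seed(param_seed(seed, j))
    par_mat[, j] <- sample_dist(specs[[j]], n_draws)
  }
  results <- NULL
  errors <- character()
  for (k in seq_len(n_draws)) {
    params <- as.list(par_mat[k, ])
    res <- tryCatch(pipeline(params), error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("draw %d: %s", k, conditionMessage(res)))
      next
    }
    if (is.null(results)) {
      results <- matrix(NA_real_, n_draws, length(res),
                        dimnames = list(NULL, names(res)))
    }
    results[k, ] <- res
  }
  if (length(errors) > max_error_rate * n_draws) {
    stopf("%d of %d draws raised model errors; first: %s",
          length(errors), n_draws, errors[1])
  }
  ok <- if (is.null(results)) logical(0) else !is.na(results[, 1])
  structure(list(params = par_mat, results = results[ok, , drop = FALSE],
                 errors = errors, n_draws = n_draws, seed = seed),
            class = "mslt_draws")
}

#' Summarise Monte Carlo draws into 95 % uncertainty intervals
#'
#' Mean and empirical 2.5th/97.5th percentiles per metric.  Percentiles
#' use linear interpolation between order statistics
#' (`stats::quantile(type = 7)`), so summaries are bit-reproducible.
#'
#' @param draws A `mslt_draws`, or a numeric matrix (draws x metrics).
#' @param probs Percentile pair for the interval.
#' @return Data frame: `metric`, `mean`, `lo`, `hi`.
#' @export
summarise_draws <- function(draws, probs = c(0.025, 0.975)) {
  m <- if (inherits(draws, "mslt_draws")) draws$results else as.matrix(draws)
  out <- data.frame(
    metric = colnames(m) %||% paste0("V", seq_len(ncol(m))),
    mean = colMeans(m),
    lo = apply(m, 2, quantile, probs = probs[1], type = 7, names = FALSE),
    hi = apply(m, 2, quantile, probs = probs[2], type = 7, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Default uncertainty specifications for the pipeline
#'
#' The effect size takes a normal distribution recovered from its
#' published 95 % CI; revenue, monitoring-cost, consumption and unit-cost
#' parameters take Pert distributions at ±25 % around their means; the
#' VSLY is held fixed.  All overridable.
#'
#' @param bundle A `mslt_bundle` supplying the parameter means.
#' @return Named list of `dist_spec`s understood by [run_cba()] overrides.
#' @export
default_uncertainty_specs <- function(bundle) {
  eff <- bundle$effect
  co <- bundle$costs
  list(
    effect_relative_change = dist_normal_ci(eff$relative_change,
                                            eff$ci_low, eff$ci_high),
    pta_food_ad_revenue = dist_pert_pm25(co$pta_food_ad_revenue),
    apn_national_transport_revenue =
      dist_pert_pm25(co$apn_national_transport_revenue),
    national_monitoring_cost = dist_pert_pm25(co$national_monitoring_cost),
    consumption_scale = dist_pert_pm25(1),
    unit_cost_scale = dist_pert_pm25(1)
  )
}
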
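#' Method-of-moments beta parameters
#'
#' Solves for the beta shape parameters with a given mean and standard
#' error: with `nu = mean(1-mean)/se^2 - 1`, `alpha = mean * nu` and
#' `beta = (1-mean) * nu`. Used for probability and utility parameters in
#' the probabilistic sensitivity analysis.
#'
#' @param mean mean in (0,1)
#' @param se standard error, `se^2 < mean(1-mean)`
#' @return named numeric `c(alpha, beta)`
#' @export
#' @examples
#' fit_beta_from_moments(0.2, 0.05)   # alpha 12.6, beta 50.4
fit_beta_from_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1) domain_error("beta mean must lie in (0,1)")
  if (se <= 0) domain_error("se must be > 0")
  if (se^2 >= mean * (1 - mean))
    domain_error(sprintf("infeasible moments: se^2 = %g >= mean(1-mean) = %g",
                         se^2, mean * (1 - mean)))
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments gamma parameters
#'
#' `shape = (mean/se)^2`, `scale = se^2/mean`. Used for cost parameters
#' in the probabilistic sensitivity analysis.
#'
#' @param mean mean > 0
#' @param se standard error > 0
#' @return named numeric `c(shape, scale)`
#' @export
#' @examples
#' fit_gamma_from_moments(1000, 200)  # shape 25, scale 40
fit_gamma_from_moments <- function(mean, se) {
  if (mean <= 0 || se <= 0) domain_error("gamma mean and se must be > 0")
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Draw one parameter set from a PSA specification
#'
#' Each entry of the spec is keyed by a dotted parameter path (as for
#' [set_param()]) plus the pseudo-path `"turnover_cost_multiplier"`,
#' which is not a config field but the multiplier passed to
#' [accumulate_outcomes()]. Families: `fixed` returns the mean; `beta`
#' and `gamma` are parameterised from (mean, se) by method of moments;
#' `uniform` samples (low, high). Draws use the current RNG stream, so
#' reproducibility is controlled by the caller's seed.
#'
#' @param spec_set named list of distribution specs (`cfg$psa`)
#' @return named numeric vector of sampled values, one per spec entry
#' @export
sample_parameter_draw <- function(spec_set) {
  vapply(spec_set, function(spec) {
    switch(spec$family,
      fixed = spec$mean,
      beta = {
        ab <- fit_beta_from_moments(spec$mean, spec$se)
        rbeta(1, ab[["alpha"]], ab[["beta"]])
      },
      gamma = {
        ss <- fit_gamma_from_moments(spec$mean, spec$se)
        rgamma(1, shape = ss[["shape"]], scale = ss[["scale"]])
      },
      uniform = runif(1, spec$low, spec$high),
      domain_error(sprintf("unknown distribution family '%s'", spec$family))
    )
  }, numeric(1))
}

# apply a draw to a config; returns list(cfg = ..., multiplier = ...)
apply_parameter_draw <- function(cfg, draw) {
  multiplier <- turnover_midpoint(cfg)
  for (path in names(draw)) {
    if (path == "turnover_cost_multiplier") {
      multiplier <- draw[[path]]
    } else {
      cfg <- set_param(cfg, path, draw[[path]])
    }
  }
  list(cfg = cfg, multiplier = multiplier)
}

#' Equal-tailed credible interval by nearest rank
#'
#' Deterministic, interpolation-free percentiles: the lower bound is the
#' sorted sample value at rank `ceiling((1-level)/2 * n)` and the upper
#' at rank `ceiling((1+level)/2 * n)`.
#'
#' @param samples numeric vector, length >= 2
#' @param level interval mass (default 0.95)
#' @return numeric `c(low, high)`
#' @export
credible_interval <- function(samples, level = 0.95) {
  n <- length(samples)
  if (n < 2) domain_error("credible_interval needs at least 2 samples")
  s <- sort(samples)
  # epsilon guards the ceiling against float noise in (1 +/- level)/2 * n
  lo <- max(1L, ceiling((1 - level) / 2 * n - 1e-9))
  hi <- min(n, ceiling((1 + level) / 2 * n - 1e-9))
  c(low = s[lo], high = s[hi])
}

PSA_OUTCOMES <- c("cost_total", "cost_lpt", "cost_turnover", "cost_service",
                  "cost_antidepressant", "qalys")

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: each iteration
#' samples one value per PSA spec entry, rebuilds the model, runs the
#' cohort and accumulates outcomes. Summaries are the mean and the
#' equal-tailed 95% credible interval of each outcome across iterations.
#' Iterations whose draw makes the transition rows infeasible are
#' redrawn (at most 10 times each, then a hard error); redraws are
#' counted in the result.
#'
#' Iteration i reseeds the RNG deterministically from `(seed, i)`, so
#' results are reproducible and independent of iteration order.
#'
#' @param cfg a validated `scenario_config`
#' @param n_iterations number of Monte Carlo iterations (>= 2)
#' @param seed integer seed
#' @return a `psa_result`: `draws` (one row per iteration, cost
#'   components + QALYs), `summaries` (mean, low, high per outcome),
#'   `n_iterations`, `seed`, `n_redraws`, plus stratum labels and horizon
#' @export
run_psa <- function(cfg, n_iterations = 1000L, seed = cfg$run$seed) {
  if (n_iterations < 2) domain_error("n_iterations must be >= 2")
  draws <- matrix(NA_real_, n_iterations, length(PSA_OUTCOMES),
                  dimnames = list(NULL, PSA_OUTCOMES))
  n_redraws <- 0L
  for (i in seq_len(n_iterations)) {
    set.seed((seed + i - 1L) %% 2147483647L)
    attempt <- 0L
    repeat {
      dr <- sample_parameter_draw(cfg$psa)
      ap <- apply_parameter_draw(cfg, dr)
      out <- tryCatch({
        tr <- run_cohort(ap$cfg)
        accumulate_outcomes(tr, ap$cfg, ap$multiplier)
      }, depcohort_infeasible_error = function(e) e)
      if (!inherits(out, "condition")) break
      attempt <- attempt + 1L
      n_redraws <- n_redraws + 1L
      if (attempt > 10L)
        infeasible_error(sprintf("iteration %d: infeasible parameters after 10 redraws", i))
    }
    draws[i, ] <- vapply(PSA_OUTCOMES, function(f) out[[f]], numeric(1))
  }
  draws <- as.data.frame(draws)
  summaries <- do.call(rbind, lapply(PSA_OUTCOMES, function(f) {
    ci <- credible_interval(draws[[f]], 0.95)
    data.frame(outcome = f, mean = mean(draws[[f]]),
               low = ci[["low"]], high = ci[["high"]],
               stringsAsFactors = FALSE)
  }))
  structure(list(
    draws = draws, summaries = summaries,
    n_iterations = as.integer(n_iterations), seed = as.integer(seed),
    n_redraws = n_redraws,
    scenario = cfg$scenario, occupation = cfg$occupation,
    horizon = cfg$run$horizon
  ), class = "psa_result")
}

#' Compare absenteeism and presenteeism PSA results
#'
#' Mean differences (absenteeism minus presenteeism), credible-interval
#' overlap per outcome, and the incremental cost-effectiveness ratio
#' when the QALY difference is non-zero.
#'
#' @param abs_result,pres_result `psa_result` objects for the two
#'   scenarios on the same horizon and occupation
#' @return a `scenario_comparison`
#' @export
compare_scenarios <- function(abs_result, pres_result) {
  if (abs_result$horizon != pres_result$horizon)
    domain_error("results have different horizons")
  if (abs_result$occupation != pres_result$occupation)
    domain_error("results have different occupations")
  sa <- abs_result$summaries; sp <- pres_result$summaries
  stopifnot(identical(sa$outcome, sp$outcome))
  overlap <- sa$low <= sp$high & sp$low <= sa$high
  names(overlap) <- sa$outcome
  delta_cost <- sa$mean[sa$outcome == "cost_total"] - sp$mean[sp$outcome == "cost_total"]
  delta_qaly <- sa$mean[sa$outcome == "qalys"] - sp$mean[sp$outcome == "qalys"]
  structure(list(
    occupation = abs_result$occupation,
    horizon = abs_result$horizon,
    delta_cost = delta_cost,
    delta_qaly = delta_qaly,
    ci_overlap = overlap,
    icer = if (delta_qaly != 0) delta_cost / delta_qaly else NA_real_
  ), class = "scenario_comparison")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s / %s-collar, %d cycles, %d iterations (seed %d, %d redraws)\n",
              x$scenario, x$occupation, x$horizon, x$n_iterations, x$seed, x$n_redraws))
  s <- x$summaries
  s[, c("mean", "low", "high")] <- round(s[, c("mean", "low", "high")], 2)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> %s-collar, %d cycles\n", x$occupation, x$horizon))
  cat(sprintf("  delta cost (abs - pres): %.0f AUD/worker\n", x$delta_cost))
  cat(sprintf("  delta QALYs:             %.3f /worker\n", x$delta_qaly))
  cat(sprintf("  ICER: %s\n", if (is.na(x$icer)) "undefined (no QALY difference)"
              else sprintf("%.0f AUD/QALY", x$icer)))
  cat("  credible intervals overlap:\n")
  print(x$ci_overlap)
  invisible(x)
}
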
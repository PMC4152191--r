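#' Specify a one-way sensitivity sweep
#'
#' @param parameter dotted parameter path (see [set_param()]); the
#'   pseudo-path `"turnover_cost_multiplier"` sweeps the turnover cost
#'   multiplier used at accumulation time
#' @param values ordered vector of alternative values (>= 1)
#' @param applies_to label recording which stratum of workers the swept
#'   parameter concerns (`"depressed"`, `"not_depressed"` or `"both"`);
#'   informational — the path itself determines what changes
#' @return a `sweep_spec`
#' @export
sweep_spec <- function(parameter, values, applies_to = "both") {
  if (length(values) < 1) domain_error("sweep needs at least one value")
  if (!applies_to %in% c("depressed", "not_depressed", "both"))
    domain_error("applies_to must be depressed, not_depressed or both")
  structure(list(parameter = parameter, values = values, applies_to = applies_to),
            class = "sweep_spec")
}

# deterministic run of one config with an optional multiplier override
run_deterministic <- function(cfg, multiplier = turnover_midpoint(cfg)) {
  accumulate_outcomes(run_cohort(cfg), cfg, multiplier)
}

#' One-way (univariate) sensitivity analysis
#'
#' Reruns the deterministic model (no PSA) for each value of a single
#' parameter, all other parameters held at base values, for both the
#' absenteeism and presenteeism configurations. The row at the
#' parameter's baseline value (if present in the sweep) is flagged.
#'
#' @param cfg_abs,cfg_pres absenteeism and presenteeism
#'   `scenario_config`s for the same occupation and horizon
#' @param sweep a [sweep_spec()]
#' @return a `sweep_result` data.frame: one row per (value x scenario)
#'   with per-worker total cost and QALYs
#' @export
one_way_sensitivity <- function(cfg_abs, cfg_pres, sweep) {
  cfgs <- list(cfg_abs, cfg_pres)
  is_mult <- sweep$parameter == "turnover_cost_multiplier"
  rows <- list()
  for (cfg in cfgs) {
    base_val <- if (is_mult) turnover_midpoint(cfg) else get_param(cfg, sweep$parameter)
    for (val in sweep$values) {
      if (is_mult) {
        out <- run_deterministic(cfg, multiplier = val)
      } else {
        out <- run_deterministic(set_param(cfg, sweep$parameter, val))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = sweep$parameter, applies_to = sweep$applies_to,
        value = val, scenario = cfg$scenario, occupation = cfg$occupation,
        cost_total = out$cost_total, qalys = out$qalys,
        baseline = isTRUE(all.equal(val, base_val)),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("sweep_result", class(res))
  res
}

#' Uniform-wage sweep across occupations
#'
#' Replaces daily wage and annual salary with values shared by blue- and
#' white-collar workers and reruns both occupation models, to test
#' whether cost differences between occupations are driven by the
#' white-collar wage premium alone.
#'
#' @param cfg_blue,cfg_white validated configs for the two occupations
#'   (same scenario)
#' @param common_wage shared daily wage (AUD/day)
#' @param common_salary shared annual salary (AUD/year)
#' @return a `sweep_result` data.frame, one row per occupation
#' @export
uniform_wage_sweep <- function(cfg_blue, cfg_white, common_wage, common_salary) {
  rows <- lapply(list(cfg_blue, cfg_white), function(cfg) {
    cfg <- set_param(cfg, "costs.daily_wage", common_wage)
    cfg <- set_param(cfg, "costs.annual_salary", common_salary)
    out <- run_deterministic(cfg)
    data.frame(
      parameter = "uniform_income", applies_to = "both",
      value = common_wage, scenario = cfg$scenario, occupation = cfg$occupation,
      cost_total = out$cost_total, qalys = out$qalys,
      baseline = FALSE, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$common_salary <- common_salary
  class(res) <- c("sweep_result", class(res))
  res
}
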
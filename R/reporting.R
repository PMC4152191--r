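write_manifest <- function(out_dir, command, config_paths, seed = NULL,
                           n_iterations = NULL) {
  manifest <- list(
    command = command,
    config_paths = as.list(config_paths),
    seed = seed,
    n_iterations = n_iterations,
    tool_version = as.character(packageVersion("depcohort")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Deterministic scenario run with file outputs
#'
#' Loads and validates a scenario file, runs the cohort, accumulates
#' outcomes at point estimates, and writes to `out_dir`: `outcome.json`
#' (per-worker discounted cost components and QALYs), `costs.csv` (the
#' component table), `trace.csv` (cycle, age, occupancy per state) and
#' `manifest.json`. An invalid configuration raises a
#' `depcohort_config_error` carrying the validation report.
#'
#' @param config_path path to a scenario JSON file
#' @param out_dir output directory (created if needed)
#' @param horizon optional horizon override (cycles)
#' @return the `scenario_outcome`, invisibly
#' @export
cmd_run <- function(config_path, out_dir, horizon = NULL) {
  cfg <- load_scenario(config_path)
  if (!is.null(horizon)) cfg$run$horizon <- as.integer(horizon)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trace <- run_cohort(cfg)
  outcome <- accumulate_outcomes(trace, cfg)
  jsonlite::write_json(unclass(outcome), file.path(out_dir, "outcome.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(outcome_table(outcome), file.path(out_dir, "costs.csv"), row.names = FALSE)
  write.csv(as.data.frame(trace), file.path(out_dir, "trace.csv"), row.names = FALSE)
  write_manifest(out_dir, "run", config_path, seed = cfg$run$seed)
  invisible(outcome)
}

#' PSA table: estimate and 95% credible interval per outcome
#'
#' @param result a `psa_result`
#' @return data.frame with scenario, occupation, outcome, estimate,
#'   interval bounds
#' @export
psa_table <- function(result) {
  s <- result$summaries
  data.frame(scenario = result$scenario, occupation = result$occupation,
             horizon = result$horizon, outcome = s$outcome,
             estimate = s$mean, ci_low = s$low, ci_high = s$high,
             stringsAsFactors = FALSE)
}

#' Compare two scenario files by PSA, with file outputs
#'
#' Runs independent probabilistic sensitivity analyses for the
#' absenteeism and presenteeism configurations (which must share horizon
#' and occupation) and writes to `out_dir`: `summary.csv` (estimate +
#' 95% credible interval per scenario and outcome), `comparison.json`
#' (mean differences, interval overlap, ICER), per-iteration draws CSVs,
#' and `manifest.json`.
#'
#' @param abs_config,pres_config paths to the two scenario JSON files
#' @param out_dir output directory (created if needed)
#' @param n_iterations Monte Carlo iterations (warns below 100, where
#'   nearest-rank interval endpoints are unstable)
#' @param seed integer seed; by default the two scenarios use offset
#'   (independent) streams
#' @param paired if TRUE, both scenarios share the same random stream
#'   (common random numbers, a variance-reduction option)
#' @return the `scenario_comparison`, invisibly
#' @export
cmd_compare <- function(abs_config, pres_config, out_dir,
                        n_iterations = 1000L, seed = 0L, paired = FALSE) {
  cfg_a <- load_scenario(abs_config)
  cfg_p <- load_scenario(pres_config)
  if (cfg_a$run$horizon != cfg_p$run$horizon)
    domain_error("configs have different horizons")
  if (n_iterations < 100)
    warning("n_iterations < 100: credible-interval endpoints are unstable")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # independent streams (no common random numbers) unless paired
  res_a <- run_psa(cfg_a, n_iterations, seed = seed)
  res_p <- run_psa(cfg_p, n_iterations,
                   seed = if (paired) seed else seed + 500000L)
  cmp <- compare_scenarios(res_a, res_p)
  write.csv(rbind(psa_table(res_a), psa_table(res_p)),
            file.path(out_dir, "summary.csv"), row.names = FALSE)
  write.csv(res_a$draws, file.path(out_dir, "draws_absenteeism.csv"), row.names = FALSE)
  write.csv(res_p$draws, file.path(out_dir, "draws_presenteeism.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(occupation = cmp$occupation, horizon = cmp$horizon,
         delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
         ci_overlap = as.list(cmp$ci_overlap), icer = cmp$icer),
    file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(out_dir, "compare", c(abs_config, pres_config),
                 seed = seed, n_iterations = n_iterations)
  invisible(cmp)
}
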
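REQUIRED_TOP_KEYS <- c("scenario", "occupation", "states", "initial",
                       "transitions", "costs", "utilities")

RUN_DEFAULTS <- list(
  cohort_size = 1000L,
  cycle_length = 0.25,
  horizon = 20L,
  annual_discount_rate = 0.03,
  half_cycle_correction = FALSE,
  seed = 1L
)

as_named_numeric <- function(x, what) {
  if (is.null(x)) config_error(sprintf("missing required key '%s'", what), field = what)
  v <- unlist(x)
  if (length(v) == 0) return(setNames(numeric(0), character(0)))
  if (is.null(names(v)) || any(names(v) == ""))
    config_error(sprintf("'%s' must be a named map", what), field = what)
  storage.mode(v) <- "double"
  v
}

as_states_df <- function(x) {
  if (is.null(x)) config_error("missing required key 'states'", field = "states")
  if (!is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(s) {
      as.data.frame(s[c("name", "alive", "depressed", "in_treatment",
                        "absorbing", "employed")], stringsAsFactors = FALSE)
    }))
  }
  need <- c("name", "alive", "depressed", "in_treatment", "absorbing", "employed")
  miss <- setdiff(need, names(x))
  if (length(miss))
    config_error(sprintf("states table missing column(s): %s", paste(miss, collapse = ", ")),
                 field = "states")
  x$name <- as.character(x$name)
  for (f in need[-1]) x[[f]] <- as.logical(x[[f]])
  rownames(x) <- NULL
  x[, need]
}

as_mortality_df <- function(x) {
  if (is.null(x)) config_error("missing required key 'transitions.baseline_mortality_annual'",
                               field = "transitions.baseline_mortality_annual")
  if (!is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(b)
      as.data.frame(b[c("age_lo", "age_hi", "male", "female")])))
  }
  need <- c("age_lo", "age_hi", "male", "female")
  miss <- setdiff(need, names(x))
  if (length(miss))
    config_error(sprintf("mortality table missing column(s): %s", paste(miss, collapse = ", ")),
                 field = "transitions.baseline_mortality_annual")
  for (f in need) x[[f]] <- as.numeric(x[[f]])
  rownames(x) <- NULL
  x[order(x$age_lo), need]
}

#' Construct a scenario configuration
#'
#' Assembles and normalises the full parameter set for one
#' (scenario x occupation) stratum. Most users will not call this
#' directly but go through [load_scenario()] or
#' [generate_scenario_set()].
#'
#' @param scenario `"absenteeism"` or `"presenteeism"`
#' @param occupation `"blue"`, `"white"` or `"pooled"`
#' @param states state roster (see [default_states()])
#' @param initial named numeric, initial probability per state (sums to 1)
#' @param transitions list of transition parameters (12-month remission /
#'   relapse / treatment-initiation probabilities, annual mortality table
#'   by age band and sex, suicide mortality multiplier, annual
#'   early-retirement probability applied while cohort age < 50,
#'   `cohort_start_age`, `sex_mix` = proportion female)
#' @param costs list of cost parameters (days per cycle, daily wage,
#'   annual salary, 12-month turnover probabilities, turnover-cost
#'   multiplier range, service contact and unit-cost maps, antidepressant
#'   use probability and script cost); all monetary values 2007 AUD
#' @param utilities named numeric, utility in \[0,1\] per state per year
#' @param psa named list of distribution specs keyed by parameter path
#'   (see [sample_parameter_draw()])
#' @param run run settings: `cohort_size` (default 1000), `cycle_length`
#'   in years (default 0.25), `horizon` in cycles (default 20),
#'   `annual_discount_rate` (default 0.03), `half_cycle_correction`
#'   (default FALSE), `seed`
#' @return an object of class `scenario_config`
#' @export
scenario_config <- function(scenario, occupation, states, initial,
                            transitions, costs, utilities,
                            psa = list(), run = list()) {
  cfg <- list(
    scenario = scenario,
    occupation = occupation,
    states = as_states_df(states),
    initial = as_named_numeric(initial, "initial"),
    transitions = transitions,
    costs = costs,
    utilities = as_named_numeric(utilities, "utilities"),
    psa = psa,
    run = utils::modifyList(RUN_DEFAULTS, run)
  )
  cfg$transitions$baseline_mortality_annual <-
    as_mortality_df(cfg$transitions$baseline_mortality_annual)
  cfg$costs$turnover_cost_multiplier_range <-
    as.numeric(unlist(cfg$costs$turnover_cost_multiplier_range))
  cfg$costs$turnover_probability_12m_not_depressed <-
    cfg$costs$turnover_probability_12m_not_depressed %||% 0
  cfg$costs$service_contacts_per_year <-
    as_named_numeric(cfg$costs$service_contacts_per_year %||% list(),
                     "costs.service_contacts_per_year")
  cfg$costs$service_unit_costs <-
    as_named_numeric(cfg$costs$service_unit_costs %||% list(),
                     "costs.service_unit_costs")
  class(cfg) <- "scenario_config"
  cfg
}

#' Load a scenario configuration from JSON
#'
#' Reads, normalises and validates a scenario file. The canonical format
#' is JSON with top-level keys `scenario`, `occupation`, `states`,
#' `initial`, `transitions`, `costs`, `utilities`, `psa`, `run`; a schema
#' description ships in `inst/extdata/scenario-schema.json`. Optional run
#' settings take documented defaults (N = 1000, 3-month cycles, 20-cycle
#' horizon, 3% annual discount rate, no half-cycle correction).
#'
#' @param path path to a JSON scenario file
#' @param validate if TRUE (default) raise a configuration error listing
#'   all invariant violations
#' @return a validated `scenario_config`
#' @export
load_scenario <- function(path, validate = TRUE) {
  if (!file.exists(path))
    config_error(sprintf("scenario file not found: %s", path), field = "path")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  cfg <- as_scenario_config(raw)
  if (validate) {
    rep <- validate_scenario(cfg)
    if (nrow(rep) > 0)
      config_error(paste0("invalid scenario configuration:\n",
                          paste(sprintf("  - %s: %s", rep$field, rep$rule), collapse = "\n")),
                   field = rep$field[1])
  }
  cfg
}

# normalise a raw (parsed-JSON or hand-built) list into a scenario_config
as_scenario_config <- function(raw) {
  if (inherits(raw, "scenario_config")) return(raw)
  miss <- setdiff(REQUIRED_TOP_KEYS, names(raw))
  if (length(miss))
    config_error(sprintf("missing required key '%s'", miss[1]), field = miss[1])
  scenario_config(
    scenario = as.character(raw$scenario),
    occupation = as.character(raw$occupation),
    states = raw$states,
    initial = raw$initial,
    transitions = raw$transitions,
    costs = raw$costs,
    utilities = raw$utilities,
    psa = raw$psa %||% list(),
    run = lapply(raw$run %||% list(), function(v) if (is.list(v)) unlist(v) else v)
  )
}

#' Write a scenario configuration to JSON
#'
#' Inverse of [load_scenario()]: `load_scenario(save_scenario(cfg, f))`
#' reproduces every field.
#'
#' @param cfg a `scenario_config`
#' @param path output file path
#' @return `path`, invisibly
#' @export
save_scenario <- function(cfg, path) {
  out <- unclass(cfg)
  out$initial <- as.list(out$initial)
  out$utilities <- as.list(out$utilities)
  out$costs$service_contacts_per_year <- as.list(out$costs$service_contacts_per_year)
  out$costs$service_unit_costs <- as.list(out$costs$service_unit_costs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

violation <- function(field, value, rule) {
  data.frame(field = field,
             value = paste(format(value), collapse = ", "),
             rule = rule, stringsAsFactors = FALSE)
}

# parameter paths whose support is the unit interval (beta-eligible in PSA)
is_unit_interval_param <- function(path) {
  if (path %in% c("transitions.suicide_mortality_multiplier",
                  "transitions.cohort_start_age")) return(FALSE)
  grepl("^utilities\\.", path) ||
    grepl("^transitions\\.(remission|relapse|treatment_initiation)", path) ||
    path %in% c("transitions.early_retirement_annual", "transitions.sex_mix",
                "costs.turnover_probability_12m",
                "costs.turnover_probability_12m_not_depressed",
                "costs.antidepressant_use_prob_2wk")
}

#' Validate a scenario configuration
#'
#' Checks every structural invariant of the parameter model and returns
#' the violations as data, one row per violation, with the offending
#' field, its value and the rule broken. An empty report means the
#' configuration is valid. Violations are data, not exceptions: callers
#' that want an error use [load_scenario()].
#'
#' @param cfg a structurally complete `scenario_config`
#' @return data.frame with columns `field`, `value`, `rule`
#' @export
validate_scenario <- function(cfg) {
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- violation(...)

  if (!cfg$scenario %in% c("absenteeism", "presenteeism"))
    add("scenario", cfg$scenario, "must be 'absenteeism' or 'presenteeism'")
  if (!cfg$occupation %in% c("blue", "white", "pooled"))
    add("occupation", cfg$occupation, "must be 'blue', 'white' or 'pooled'")

  st <- cfg$states
  if (anyDuplicated(st$name)) add("states", st$name, "state names must be unique")
  dec <- st$name == "deceased"
  if (sum(dec) != 1) {
    add("states", sum(dec), "exactly one state must be named 'deceased'")
  } else if (st$alive[dec]) {
    add("states.deceased.alive", TRUE, "'deceased' must have alive = FALSE")
  }
  if ("retired" %in% st$name) {
    r <- st[st$name == "retired", ]
    if (!r$absorbing || !r$alive)
      add("states.retired", c(r$absorbing, r$alive), "'retired' must be absorbing and alive")
  }
  bad <- st$absorbing & st$employed
  if (any(bad)) add("states", st$name[bad], "absorbing states cannot be employed")
  bad <- !st$alive & (st$depressed | st$in_treatment)
  if (any(bad)) add("states", st$name[bad],
                    "depressed/in_treatment must be FALSE for non-alive states")

  ini <- cfg$initial
  unknown <- setdiff(names(ini), st$name)
  if (length(unknown)) add("initial", unknown, "references unknown state(s)")
  if (any(ini < 0 | ini > 1)) add("initial", ini, "probabilities must lie in [0,1]")
  s <- sum(ini)
  if (abs(s - 1) > 1e-9) add("initial", s, sprintf("initial distribution sums to %g", s))
  absorbing_named <- intersect(names(ini), st$name[st$absorbing])
  if (length(absorbing_named) && any(ini[absorbing_named] != 0))
    add("initial", ini[absorbing_named], "absorbing states must start empty")

  tr <- cfg$transitions
  for (f in c("remission_treated_12m", "remission_untreated_12m",
              "relapse_treated_12m", "relapse_untreated_12m",
              "treatment_initiation_12m", "early_retirement_annual", "sex_mix")) {
    x <- tr[[f]]
    if (is.null(x)) add(paste0("transitions.", f), NULL, "missing")
    else if (x < 0 || x > 1) add(paste0("transitions.", f), x, "must lie in [0,1]")
  }
  if (is.null(tr$suicide_mortality_multiplier) || tr$suicide_mortality_multiplier < 1)
    add("transitions.suicide_mortality_multiplier", tr$suicide_mortality_multiplier,
        "must be >= 1")
  if (is.null(tr$cohort_start_age) || tr$cohort_start_age <= 0)
    add("transitions.cohort_start_age", tr$cohort_start_age, "must be > 0")
  mt <- tr$baseline_mortality_annual
  if (is.null(mt) || nrow(mt) == 0) {
    add("transitions.baseline_mortality_annual", NULL, "missing or empty")
  } else {
    if (any(mt$male < 0 | mt$male > 1 | mt$female < 0 | mt$female > 1))
      add("transitions.baseline_mortality_annual", NULL, "rates must lie in [0,1]")
    if (any(mt$age_hi <= mt$age_lo))
      add("transitions.baseline_mortality_annual", NULL, "age bands must have age_hi > age_lo")
  }

  co <- cfg$costs
  cl <- cfg$run$cycle_length
  for (f in c("absenteeism_days_per_cycle", "presenteeism_days_per_cycle")) {
    x <- co[[f]]
    if (is.null(x)) add(paste0("costs.", f), NULL, "missing")
    else if (x < 0 || x > 365 * cl)
      add(paste0("costs.", f), x, sprintf("days per cycle must lie in [0, %g]", 365 * cl))
  }
  for (f in c("daily_wage", "annual_salary", "antidepressant_script_cost_3m")) {
    x <- co[[f]]
    if (is.null(x)) add(paste0("costs.", f), NULL, "missing")
    else if (x < 0) add(paste0("costs.", f), x, "must be >= 0")
  }
  for (f in c("turnover_probability_12m", "turnover_probability_12m_not_depressed",
              "antidepressant_use_prob_2wk")) {
    x <- co[[f]]
    if (is.null(x)) add(paste0("costs.", f), NULL, "missing")
    else if (x < 0 || x > 1) add(paste0("costs.", f), x, "must lie in [0,1]")
  }
  rg <- co$turnover_cost_multiplier_range
  if (length(rg) != 2 || rg[1] > rg[2])
    add("costs.turnover_cost_multiplier_range", rg, "must be (low, high) with low <= high")
  if (!setequal(names(co$service_contacts_per_year), names(co$service_unit_costs)))
    add("costs.service_unit_costs", names(co$service_unit_costs),
        "provider keys must match service_contacts_per_year")
  if (any(co$service_contacts_per_year < 0)) add("costs.service_contacts_per_year",
                                                 co$service_contacts_per_year, "must be >= 0")
  if (any(co$service_unit_costs < 0)) add("costs.service_unit_costs",
                                          co$service_unit_costs, "must be >= 0")

  ut <- cfg$utilities
  unknown <- setdiff(names(ut), st$name)
  if (length(unknown)) add("utilities", unknown, "references unknown state(s)")
  if (any(ut < 0 | ut > 1)) add("utilities", ut, "utilities must lie in [0,1]")
  if ("deceased" %in% names(ut) && ut[["deceased"]] != 0)
    add("utilities.deceased", ut[["deceased"]], "deceased utility must be 0")

  for (p in names(cfg$psa)) {
    spec <- cfg$psa[[p]]
    fam <- spec$family %||% NA_character_
    fld <- paste0("psa.", p)
    if (!fam %in% c("beta", "gamma", "uniform", "fixed")) {
      add(fld, fam, "family must be beta, gamma, uniform or fixed")
      next
    }
    if (fam == "beta") {
      if (!is_unit_interval_param(p)) add(fld, fam, "beta family on unbounded parameter")
      m <- spec$mean; se <- spec$se
      if (is.null(m) || m <= 0 || m >= 1) add(fld, m, "beta mean must lie in (0,1)")
      else if (is.null(se) || se <= 0) add(fld, se, "beta se must be > 0")
      else if (se^2 >= m * (1 - m)) add(fld, se, "beta se too large: se^2 must be < mean(1-mean)")
    } else if (fam == "gamma") {
      if (is_unit_interval_param(p) && !grepl("days_per_cycle$", p))
        add(fld, fam, "gamma family on probability parameter; use beta")
      if (is.null(spec$mean) || spec$mean <= 0) add(fld, spec$mean, "gamma mean must be > 0")
      if (is.null(spec$se) || spec$se <= 0) add(fld, spec$se, "gamma se must be > 0")
    } else if (fam == "uniform") {
      if (is.null(spec$low) || is.null(spec$high) || spec$low > spec$high)
        add(fld, c(spec$low, spec$high), "uniform requires low <= high")
    }
  }

  run <- cfg$run
  if (run$horizon < 1) add("run.horizon", run$horizon, "must be >= 1")
  if (run$cohort_size < 1) add("run.cohort_size", run$cohort_size, "must be >= 1")
  if (run$annual_discount_rate < 0 || run$annual_discount_rate >= 1)
    add("run.annual_discount_rate", run$annual_discount_rate, "must lie in [0,1)")
  if (run$cycle_length <= 0) add("run.cycle_length", run$cycle_length, "must be > 0")

  if (length(v) == 0)
    return(data.frame(field = character(), value = character(), rule = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s / %s-collar\n", x$scenario, x$occupation))
  cat(sprintf("  states: %s\n", paste(x$states$name, collapse = ", ")))
  cat(sprintf("  N = %d, %g-year cycles, horizon %d cycles, discount %.1f%%/yr\n",
              x$run$cohort_size, x$run$cycle_length, x$run$horizon,
              100 * x$run$annual_discount_rate))
  invisible(x)
}
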
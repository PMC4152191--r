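# Minimal two-state chain: one live, depressed, employed state plus
# deceased. Per-cycle death probability is controlled exactly by setting
# the annual probability to 1-(1-q)^(1/cycle_length). Lost productive
# time is the only active cost channel (days x wage).
toy_chain_config <- function(death_per_cycle = 0.1, days = 5, wage = 20,
                             utility = 0.6, horizon = 4L, rate = 0,
                             cycle_length = 0.25) {
  p_annual <- 1 - (1 - death_per_cycle)^(1 / cycle_length)
  scenario_config(
    scenario = "absenteeism", occupation = "pooled",
    states = data.frame(
      name = c("alive", "deceased"),
      alive = c(TRUE, FALSE), depressed = c(TRUE, FALSE),
      in_treatment = c(FALSE, FALSE), absorbing = c(FALSE, TRUE),
      employed = c(TRUE, FALSE), stringsAsFactors = FALSE
    ),
    initial = c(alive = 1, deceased = 0),
    transitions = list(
      remission_treated_12m = 0, remission_untreated_12m = 0,
      relapse_treated_12m = 0, relapse_untreated_12m = 0,
      treatment_initiation_12m = 0,
      baseline_mortality_annual = data.frame(
        age_lo = 15, age_hi = 120, male = p_annual, female = p_annual),
      suicide_mortality_multiplier = 1,
      early_retirement_annual = 0,
      cohort_start_age = 40, sex_mix = 0.5
    ),
    costs = list(
      absenteeism_days_per_cycle = days, presenteeism_days_per_cycle = 0,
      daily_wage = wage, annual_salary = 0,
      turnover_probability_12m = 0,
      turnover_cost_multiplier_range = c(1, 1),
      service_contacts_per_year = list(), service_unit_costs = list(),
      antidepressant_use_prob_2wk = 0, antidepressant_script_cost_3m = 0
    ),
    utilities = c(alive = utility, deceased = 0),
    run = list(horizon = as.integer(horizon), annual_discount_rate = rate,
               cycle_length = cycle_length)
  )
}

# fixture quadruple, loaded once per test session
fixture_env <- new.env()
get_fixture <- function() {
  if (is.null(fixture_env$fx)) fixture_env$fx <- packaged_fixture()
  fixture_env$fx
}

# a single generated config, default stratum
gen_one <- function(seed = 1, ...) generate_scenario_set(seed, ...)$abs_blue

# replace a config's PSA spec by point-mass ("fixed") entries at the
# config's own base values, keeping the same parameter paths
fix_psa_at_base <- function(cfg) {
  cfg$psa <- lapply(setNames(names(cfg$psa), names(cfg$psa)), function(path) {
    m <- if (path == "turnover_cost_multiplier") turnover_midpoint(cfg)
         else get_param(cfg, path)
    list(family = "fixed", mean = m)
  })
  cfg
}

save_and_read <- function(cfg, f) {
  save_scenario(cfg, f)
  f
}

as_scenario_config_roundtrip <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  save_scenario(cfg, f)
  load_scenario(f)
}

expect_no_violations <- function(cfg) {
  rep <- validate_scenario(cfg)
  testthat::expect_equal(nrow(rep), 0, info = paste(rep$field, rep$rule, collapse = "; "))
}
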
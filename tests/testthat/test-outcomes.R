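state_row <- function(name, states = default_states()) states[states$name == name, ]

test_that("discount factors follow end-of-cycle annual compounding", {
  expect_equal(discount_factor(1:20, 0, 0.25), rep(1, 20))
  expect_equal(discount_factor(4, 0.03, 0.25), 1 / 1.03, tolerance = 1e-9)
  expect_equal(discount_factor(20, 0.03, 0.25), 1.03^-5, tolerance = 1e-9)
  expect_equal(discount_factor(20, 0.03, 0.25), 0.862609, tolerance = 1e-6 / 0.862609)
  expect_error(discount_factor(1, 1.2, 0.25), class = "depcohort_domain_error")
})

test_that("lost productive time is days x wage for depressed employed states only", {
  costs <- list(absenteeism_days_per_cycle = 5, presenteeism_days_per_cycle = 2,
                daily_wage = 215)
  expect_equal(lost_productive_time_cost(state_row("depressed_treated"), costs,
                                         "absenteeism"), 1075)
  expect_equal(lost_productive_time_cost(state_row("depressed_treated"), costs,
                                         "presenteeism"), 430)
  expect_equal(lost_productive_time_cost(state_row("recovered_treated"), costs,
                                         "absenteeism"), 0)
  expect_equal(lost_productive_time_cost(state_row("retired"), costs, "absenteeism"), 0)
})

test_that("turnover cost is restricted to depressed-in-treatment employed states", {
  costs <- list(turnover_probability_12m = 0.105,
                turnover_probability_12m_not_depressed = 0,
                annual_salary = 55595)
  p_cycle <- convert_probability(0.105, 1, 0.25)
  got <- expected_turnover_cost(state_row("depressed_treated"), costs, 1.0)
  expect_equal(got, p_cycle * 55595, tolerance = 1e-12)
  expect_equal(got, 1521.1, tolerance = 1 / 1521.1)  # printed-value cross-check
  expect_equal(expected_turnover_cost(state_row("depressed_untreated"), costs, 1.0), 0)
  expect_equal(expected_turnover_cost(state_row("retired"), costs, 1.0), 0)
  expect_equal(expected_turnover_cost(state_row("depressed_treated"), costs, 0), 0)
  # the default-zero channel for non-depressed workers activates on demand
  expect_equal(expected_turnover_cost(state_row("recovered_untreated"), costs, 1.0), 0)
  costs$turnover_probability_12m_not_depressed <- 0.05
  expect_equal(expected_turnover_cost(state_row("recovered_untreated"), costs, 1.0),
               convert_probability(0.05, 1, 0.25) * 55595, tolerance = 1e-12)
})

test_that("service use cost pro-rates annual contacts for in-treatment states", {
  costs <- list(service_contacts_per_year = c(gp = 4, psychologist = 8),
                service_unit_costs = c(gp = 35, psychologist = 120))
  expect_equal(service_use_cost(state_row("depressed_treated"), costs), 275)
  expect_equal(service_use_cost(state_row("depressed_untreated"), costs), 0)
  empty <- list(service_contacts_per_year = setNames(numeric(0), character(0)),
                service_unit_costs = setNames(numeric(0), character(0)))
  expect_equal(service_use_cost(state_row("depressed_treated"), empty), 0)
  bad <- list(service_contacts_per_year = c(gp = 4), service_unit_costs = c(psychologist = 1))
  expect_error(service_use_cost(state_row("depressed_treated"), bad),
               class = "depcohort_config_error")
})

test_that("antidepressant cost converts 2-week use to the cycle and prices the script", {
  costs <- list(antidepressant_use_prob_2wk = 0, antidepressant_script_cost_3m = 80)
  expect_equal(antidepressant_cost(state_row("depressed_treated"), costs), 0)
  costs$antidepressant_use_prob_2wk <- 1
  expect_equal(antidepressant_cost(state_row("depressed_treated"), costs), 80)
  costs$antidepressant_use_prob_2wk <- 0.3
  # exponent 0.25 / (2/52) = 6.5
  expect_equal(antidepressant_cost(state_row("depressed_treated"), costs),
               (1 - 0.7^6.5) * 80, tolerance = 1e-12)
  expect_equal(antidepressant_cost(state_row("recovered_untreated"), costs), 0)
})

test_that("accumulation matches hand-computed totals on degenerate cohorts", {
  # whole cohort parked in one state, utility 0.6, no discounting
  cfg <- toy_chain_config(death_per_cycle = 0, utility = 0.6, horizon = 4L)
  out <- accumulate_outcomes(run_cohort(cfg), cfg)
  expect_equal(out$qalys, 0.6, tolerance = 1e-12)

  cfg0 <- toy_chain_config(death_per_cycle = 0, utility = 0)
  expect_equal(accumulate_outcomes(run_cohort(cfg0), cfg0)$qalys, 0)

  # death 0.1/cycle, 100/cycle while alive, rate 0: geometric sum
  cfg <- toy_chain_config(death_per_cycle = 0.1, days = 5, wage = 20, horizon = 4L)
  out <- accumulate_outcomes(run_cohort(cfg), cfg)
  expect_equal(out$cost_total, 100 * (0.9 + 0.81 + 0.729 + 0.6561), tolerance = 1e-9)
  expect_equal(out$cost_total, 309.51, tolerance = 1e-9)
  expect_equal(out$cost_lpt, out$cost_total)
})

test_that("constant payoff with discounting matches the geometric series", {
  # no dynamics, payoff c per cycle, per-cycle factor d = 1.03^(-0.25)
  cfg <- toy_chain_config(death_per_cycle = 0, days = 5, wage = 20,
                          horizon = 12L, rate = 0.03)
  out <- accumulate_outcomes(run_cohort(cfg), cfg)
  d <- 1.03^(-0.25)
  expect_equal(out$cost_total, 100 * d * (1 - d^12) / (1 - d), tolerance = 1e-9)
  expect_equal(out$qalys, 0.6 * 0.25 * d * (1 - d^12) / (1 - d), tolerance = 1e-9)
})

test_that("cost components always add to the total and QALYs stay bounded", {
  for (seed in c(21, 22, 23)) {
    cfg <- gen_one(seed)
    out <- accumulate_outcomes(run_cohort(cfg), cfg)
    expect_equal(out$cost_total,
                 out$cost_lpt + out$cost_turnover + out$cost_service + out$cost_antidepressant,
                 tolerance = 1e-12)
    expect_lte(out$qalys, cfg$run$horizon * cfg$run$cycle_length * max(cfg$utilities))
    expect_gte(out$qalys, 0)
    expect_true(all(c(out$cost_lpt, out$cost_turnover, out$cost_service,
                      out$cost_antidepressant) >= 0))
  }
})

test_that("total cost is monotone in wage, multiplier and unit costs", {
  cfg <- gen_one(30)
  base <- accumulate_outcomes(run_cohort(cfg), cfg)
  up_wage <- set_param(cfg, "costs.daily_wage", cfg$costs$daily_wage * 1.5)
  expect_gt(accumulate_outcomes(run_cohort(up_wage), up_wage)$cost_total, base$cost_total)
  expect_gt(accumulate_outcomes(run_cohort(cfg), cfg, multiplier = 3)$cost_total,
            base$cost_total)
  up_unit <- set_param(cfg, "costs.service_unit_costs.gp",
                       cfg$costs$service_unit_costs[["gp"]] * 2)
  expect_gt(accumulate_outcomes(run_cohort(up_unit), up_unit)$cost_total, base$cost_total)
})

test_that("half-cycle correction averages boundary occupancy", {
  cfg <- toy_chain_config(death_per_cycle = 0.1, horizon = 4L)
  plain <- accumulate_outcomes(run_cohort(cfg), cfg)
  cfg$run$half_cycle_correction <- TRUE
  hcc <- accumulate_outcomes(run_cohort(cfg), cfg)
  # survivors decline, so mid-cycle membership exceeds end-of-cycle
  expect_gt(hcc$cost_total, plain$cost_total)
  surv <- 0.9^(0:4)
  expect_equal(hcc$cost_total, 100 * sum((surv[1:4] + surv[2:5]) / 2), tolerance = 1e-9)
})

test_that("trace/config mismatches are rejected", {
  cfg <- gen_one(31)
  tr <- run_cohort(cfg)
  other <- toy_chain_config()
  expect_error(accumulate_outcomes(tr, other), class = "depcohort_domain_error")
  short <- cfg; short$run$horizon <- 3L
  expect_error(accumulate_outcomes(tr, short), class = "depcohort_domain_error")
})
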
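#' Per-cycle discount factor
#'
#' Payoffs accrue at cycle end; cycle 1 is the first accrual. With annual
#' rate r and cycle length L years, cycle t is discounted by
#' `(1 + r)^(-t * L)`.
#'
#' @param cycle cycle index >= 1 (vectorised)
#' @param annual_rate annual discount rate in \[0, 1)
#' @param cycle_length cycle length in years
#' @return discount factor(s)
#' @export
discount_factor <- function(cycle, annual_rate, cycle_length) {
  if (annual_rate < 0 || annual_rate >= 1) domain_error("rate must lie in [0,1)")
  (1 + annual_rate)^(-cycle * cycle_length)
}

#' Lost-productive-time cost of one state for one cycle
#'
#' Depression-specific absenteeism or presenteeism days per 3-month cycle
#' valued at the average daily wage. Only depressed, employed states
#' accrue it; the scenario selects which day count applies (the two
#' scenarios are mutually exclusive, so the other count is zero by
#' construction in generated configs).
#'
#' @param state one-row slice of the state roster
#' @param costs cost parameters (`cfg$costs`)
#' @param scenario `"absenteeism"` or `"presenteeism"`
#' @return AUD per person in the state per cycle
#' @export
lost_productive_time_cost <- function(state, costs, scenario) {
  if (!isTRUE(state$depressed) || !isTRUE(state$employed)) return(0)
  days <- if (scenario == "absenteeism") costs$absenteeism_days_per_cycle
          else costs$presenteeism_days_per_cycle
  days * costs$daily_wage
}

#' Expected job-turnover cost of one state for one cycle
#'
#' Recruitment/hiring/training cost of replacing a departing employee,
#' expressed as a multiple of annual salary. For depressed states the
#' 12-month turnover probability applies to 'depressed in treatment'
#' states only (the source estimate is treatment-seeking); employed
#' non-depressed states carry a separate probability that defaults to
#' zero and exists for one-way sensitivity sweeps.
#'
#' @inheritParams lost_productive_time_cost
#' @param multiplier turnover cost as a multiple of annual salary
#' @param cycle_length cycle length in years (default 0.25)
#' @return AUD per person in the state per cycle
#' @export
expected_turnover_cost <- function(state, costs, multiplier, cycle_length = 0.25) {
  if (!isTRUE(state$employed)) return(0)
  p12 <- if (isTRUE(state$depressed)) {
    if (isTRUE(state$in_treatment)) costs$turnover_probability_12m else 0
  } else {
    costs$turnover_probability_12m_not_depressed %||% 0
  }
  convert_probability(p12, 1, cycle_length) * multiplier * costs$annual_salary
}

#' Health-service use cost of one state for one cycle
#'
#' Annual contact counts with GPs, psychologists, psychiatrists, mental
#' health nurses and alternative therapists, pro-rated to the cycle and
#' valued at per-contact unit costs (Medicare Benefits Schedule style).
#' Only in-treatment states accrue service use.
#'
#' @inheritParams expected_turnover_cost
#' @return AUD per person in the state per cycle
#' @export
service_use_cost <- function(state, costs, cycle_length = 0.25) {
  if (!isTRUE(state$in_treatment)) return(0)
  contacts <- costs$service_contacts_per_year
  unit <- costs$service_unit_costs
  miss <- setdiff(names(contacts), names(unit))
  if (length(miss))
    config_error(sprintf("provider(s) without a unit cost: %s", paste(miss, collapse = ", ")),
                 field = "costs.service_unit_costs")
  if (length(contacts) == 0) return(0)
  sum(contacts * cycle_length * unit[names(contacts)])
}

#' Antidepressant medication cost of one state for one cycle
#'
#' The reported 2-week use probability is converted to a per-cycle
#' probability (constant hazard) and multiplied by the 3-month SSRI
#' script cost. In-treatment states only.
#'
#' @inheritParams expected_turnover_cost
#' @return AUD per person in the state per cycle
#' @export
antidepressant_cost <- function(state, costs, cycle_length = 0.25) {
  if (!isTRUE(state$in_treatment)) return(0)
  convert_probability(costs$antidepressant_use_prob_2wk, 2 / 52, cycle_length) *
    costs$antidepressant_script_cost_3m
}

# the four cost channels for every state, as a states x channels matrix
cycle_state_costs <- function(cfg, multiplier) {
  st <- cfg$states
  cl <- cfg$run$cycle_length
  out <- matrix(0, nrow(st), 4,
                dimnames = list(st$name, c("lpt", "turnover", "service", "antidepressant")))
  for (i in seq_len(nrow(st))) {
    s <- st[i, ]
    out[i, "lpt"] <- lost_productive_time_cost(s, cfg$costs, cfg$scenario)
    out[i, "turnover"] <- expected_turnover_cost(s, cfg$costs, multiplier, cl)
    out[i, "service"] <- service_use_cost(s, cfg$costs, cl)
    out[i, "antidepressant"] <- antidepressant_cost(s, cfg$costs, cl)
  }
  out
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' For each cycle t = 1..T and state s, adds
#' `occupancy(t, s) * cost(s) * d(t)` to each cost channel and
#' `occupancy(t, s) * utility(s) * cycle_length * d(t)` to QALYs, where
#' `d(t)` is [discount_factor()]. End-of-cycle occupancy earns the
#' cycle's payoff; cycle 0 earns nothing. With
#' `run$half_cycle_correction = TRUE` the mean of start- and end-of-cycle
#' occupancy is used instead. Totals are divided by the initial cohort
#' size, giving per-worker results; states without a configured utility
#' (e.g. deceased) accrue zero.
#'
#' @param trace a `cohort_trace` from [run_cohort()]
#' @param cfg the `scenario_config` that produced it
#' @param multiplier turnover cost multiplier; defaults to the midpoint
#'   of the configured range (the deterministic point estimate)
#' @return a `scenario_outcome`: per-worker discounted `cost_total`,
#'   `cost_lpt`, `cost_turnover`, `cost_service`, `cost_antidepressant`
#'   (2007 AUD) and `qalys`, plus the horizon and stratum labels
#' @export
accumulate_outcomes <- function(trace, cfg, multiplier = turnover_midpoint(cfg)) {
  if (!identical(colnames(trace$occupancy), cfg$states$name))
    domain_error("trace and config disagree on the state roster")
  Tn <- cfg$run$horizon
  if (nrow(trace$occupancy) != Tn + 1)
    domain_error("trace length does not match config horizon")
  cl <- cfg$run$cycle_length
  N <- cfg$run$cohort_size

  cost_mat <- cycle_state_costs(cfg, multiplier)          # states x 4
  util <- setNames(numeric(nrow(cfg$states)), cfg$states$name)
  util[names(cfg$utilities)] <- cfg$utilities
  if ("deceased" %in% names(util)) util[["deceased"]] <- 0

  occ <- trace$occupancy
  w <- occ[2:(Tn + 1), , drop = FALSE]
  if (isTRUE(cfg$run$half_cycle_correction))
    w <- (occ[1:Tn, , drop = FALSE] + w) / 2
  d <- discount_factor(1:Tn, cfg$run$annual_discount_rate, cl)

  comp <- as.vector(t(d %*% (w %*% cost_mat))) / N        # 4 channels
  names(comp) <- colnames(cost_mat)
  qalys <- sum(d * (w %*% util)) * cl / N

  structure(list(
    scenario = cfg$scenario,
    occupation = cfg$occupation,
    horizon = Tn,
    cost_lpt = comp[["lpt"]],
    cost_turnover = comp[["turnover"]],
    cost_service = comp[["service"]],
    cost_antidepressant = comp[["antidepressant"]],
    cost_total = sum(comp),
    qalys = qalys
  ), class = "scenario_outcome")
}

#' Table of per-worker cost components for one outcome
#'
#' @param outcome a `scenario_outcome`
#' @return data.frame with rows Lost Productive Time, Job Turnover,
#'   Service Use, Antidepressants, Total
#' @export
outcome_table <- function(outcome) {
  data.frame(
    component = c("Lost Productive Time", "Job Turnover", "Service Use",
                  "Antidepressants", "Total"),
    cost_aud = c(outcome$cost_lpt, outcome$cost_turnover, outcome$cost_service,
                 outcome$cost_antidepressant, outcome$cost_total),
    stringsAsFactors = FALSE
  )
}

#' @export
print.scenario_outcome <- function(x, ...) {
  cat(sprintf("<scenario_outcome> %s / %s-collar, %d cycles\n",
              x$scenario, x$occupation, x$horizon))
  tb <- outcome_table(x)
  tb$cost_aud <- round(tb$cost_aud)
  print(tb, row.names = FALSE)
  cat(sprintf("QALYs per worker: %.2f\n", x$qalys))
  invisible(x)
}
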
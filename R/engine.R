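#' Convert a probability between time periods
#'
#' Re-expresses a probability observed over one period on another period
#' under a constant-hazard assumption:
#' `p' = 1 - (1 - p)^(t_to / t_from)`. Used throughout to turn 12-month
#' transition probabilities and 2-week medication-use probabilities into
#' per-cycle (3-month) probabilities.
#'
#' @param p probability over `t_from` (vectorised)
#' @param t_from,t_to periods in the same time unit (years here), both > 0
#' @return probability over `t_to`
#' @export
#' @examples
#' convert_probability(0.105, 1, 0.25)   # annual 10.5% -> per 3-month cycle
convert_probability <- function(p, t_from, t_to) {
  if (any(p < 0 | p > 1)) domain_error("probability must lie in [0,1]")
  if (t_from <= 0 || t_to <= 0) domain_error("periods must be > 0")
  1 - (1 - p)^(t_to / t_from)
}

# annual all-cause mortality for the cohort at a given age: sex-mixed
# lookup in the age-band table (ages beyond the table clamp to the
# nearest band)
annual_mortality_at <- function(transitions, age) {
  mt <- transitions$baseline_mortality_annual
  i <- which(age >= mt$age_lo & age < mt$age_hi)
  if (length(i) == 0) i <- if (age < mt$age_lo[1]) 1L else nrow(mt)
  i <- i[1]
  f <- transitions$sex_mix
  f * mt$female[i] + (1 - f) * mt$male[i]
}

#' Build the per-cycle transition matrix
#'
#' Constructs the row-stochastic matrix governing one 3-month cycle.
#' Competing risks are resolved death-first: the per-cycle death
#' probability `q` (baseline age/sex mortality, multiplied by the suicide
#' excess in depressed states) enters the `deceased` column unscaled;
#' every other named transition `p_i` (remission, relapse, treatment
#' initiation, early retirement) receives survivor mass `(1 - q) * p_i`;
#' the self-transition takes the residual. Named transitions are never
#' rescaled against each other; if they sum above 1 the parameters are
#' infeasible and an error identifies the state.
#'
#' Early retirement applies only from employed states and only while the
#' cohort age at the start of the cycle is below 50.
#'
#' @param params transition parameters (`cfg$transitions`)
#' @param states state roster data.frame
#' @param cycle_index 0-based index of the cycle being entered; sets the
#'   cohort age used for mortality and the retirement cutoff
#' @param cfg the enclosing `scenario_config` (supplies `cycle_length`)
#' @return square matrix with state names on both dimensions
#' @export
build_transition_matrix <- function(params, states, cycle_index, cfg) {
  cl <- cfg$run$cycle_length
  age <- params$cohort_start_age + cycle_index * cl
  nm <- states$name
  S <- length(nm)
  M <- matrix(0, S, S, dimnames = list(nm, nm))

  q_base <- convert_probability(annual_mortality_at(params, age), 1, cl)
  p_remit_tr <- convert_probability(params$remission_treated_12m, 1, cl)
  p_remit_un <- convert_probability(params$remission_untreated_12m, 1, cl)
  p_rel_tr <- convert_probability(params$relapse_treated_12m, 1, cl)
  p_rel_un <- convert_probability(params$relapse_untreated_12m, 1, cl)
  p_init <- convert_probability(params$treatment_initiation_12m, 1, cl)
  p_retire <- convert_probability(params$early_retirement_annual, 1, cl)

  for (i in seq_len(S)) {
    st <- states[i, ]
    if (st$absorbing || !st$alive) {
      M[i, i] <- 1
      next
    }
    q <- if (st$depressed) min(1, q_base * params$suicide_mortality_multiplier) else q_base

    targets <- character(0); probs <- numeric(0)
    addt <- function(target, p) {
      if (!is.na(target) && p > 0) {
        targets <<- c(targets, target); probs <<- c(probs, p)
      }
    }
    if (st$depressed) {
      addt(find_state_name(states, FALSE, st$in_treatment),
           if (st$in_treatment) p_remit_tr else p_remit_un)
    } else {
      addt(find_state_name(states, TRUE, st$in_treatment),
           if (st$in_treatment) p_rel_tr else p_rel_un)
    }
    if (!st$in_treatment)
      addt(find_state_name(states, st$depressed, TRUE), p_init)
    if (st$employed && age < 50 && "retired" %in% nm)
      addt("retired", p_retire)

    if (sum(probs) > 1 + 1e-12)
      infeasible_error(sprintf(
        "named transitions from state '%s' sum to %.4f (> 1)", st$name, sum(probs)),
        state = st$name)

    if ("deceased" %in% nm) M[i, "deceased"] <- q
    for (k in seq_along(targets))
      M[i, targets[k]] <- M[i, targets[k]] + (1 - q) * probs[k]
    M[i, i] <- M[i, i] + (1 - q) * (1 - sum(probs))
  }
  M
}

#' Propagate the cohort through the model
#'
#' Distributes N workers over the states by the initial distribution and
#' applies the per-cycle transition matrix `horizon` times. Matrices are
#' rebuilt each cycle because mortality is age-banded and early
#' retirement switches off at age 50; all other parameters are
#' time-homogeneous.
#'
#' @param cfg a validated `scenario_config`
#' @return a `cohort_trace`: list with `occupancy`
#'   ((horizon+1) x states matrix of persons, rows = cycles 0..T),
#'   `cohort_age` (years at each cycle), `states`, and the `cfg` used
#' @export
run_cohort <- function(cfg) {
  st <- cfg$states
  nm <- st$name
  Tn <- cfg$run$horizon
  N <- cfg$run$cohort_size
  cl <- cfg$run$cycle_length

  v0 <- setNames(numeric(length(nm)), nm)
  v0[names(cfg$initial)] <- N * cfg$initial
  occ <- matrix(0, Tn + 1, length(nm), dimnames = list(0:Tn, nm))
  occ[1, ] <- v0
  for (t in 0:(Tn - 1)) {
    M <- build_transition_matrix(cfg$transitions, st, t, cfg)
    nxt <- drop(occ[t + 1, ] %*% M)
    if (any(nxt < -1e-9))
      stop("internal error: negative occupancy produced at cycle ", t + 1)
    occ[t + 2, ] <- pmax(nxt, 0)
  }
  structure(list(
    occupancy = occ,
    cohort_age = cfg$transitions$cohort_start_age + (0:Tn) * cl,
    states = st,
    cfg = cfg
  ), class = "cohort_trace")
}

#' Matrix-power occupancy oracle
#'
#' Computes `v0 %*% M^t` by repeated squaring — an independent
#' verification path for [run_cohort()] on time-homogeneous models (it
#' shares no code with the cycle loop).
#'
#' @param M square transition matrix
#' @param v0 occupancy vector at cycle 0
#' @param t number of cycles (non-negative integer)
#' @return occupancy vector after `t` cycles
#' @export
trace_oracle <- function(M, v0, t) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) domain_error("M must be square")
  if (length(v0) != nrow(M)) domain_error("v0 length must match M")
  if (t < 0 || t != round(t)) domain_error("t must be a non-negative integer")
  P <- diag(nrow(M))
  B <- M
  t <- as.integer(t)
  while (t > 0) {
    if (bitwAnd(t, 1L) == 1L) P <- P %*% B
    B <- B %*% B
    t <- bitwShiftR(t, 1L)
  }
  drop(v0 %*% P)
}

#' @export
print.cohort_trace <- function(x, ...) {
  Tn <- nrow(x$occupancy) - 1
  cat(sprintf("<cohort_trace> %d cycles, %d states, N = %g\n",
              Tn, ncol(x$occupancy), sum(x$occupancy[1, ])))
  cat("final occupancy:\n")
  print(round(x$occupancy[Tn + 1, ], 1))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = as.integer(rownames(x$occupancy)),
             age = x$cohort_age,
             x$occupancy,
             check.names = FALSE, row.names = NULL)
}
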
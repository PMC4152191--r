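test_that("probability-period conversion follows the constant-hazard form", {
  expect_equal(convert_probability(0.105, 1, 0.25), 1 - 0.895^0.25, tolerance = 1e-12)
  expect_equal(convert_probability(0.105, 1, 0.25), 0.02736, tolerance = 1e-5 / 0.02736)
  expect_identical(convert_probability(0, 3, 7), 0)
  expect_equal(convert_probability(1, 1, 0.25), 1)
  expect_equal(convert_probability(0.37, 2, 2), 0.37)
  expect_error(convert_probability(1.2, 1, 1), class = "depcohort_domain_error")

  # monotone in p, and 12m -> 3m -> 12m is the identity
  p <- seq(0.01, 0.99, length.out = 50)
  q <- convert_probability(p, 1, 0.25)
  expect_true(all(diff(q) > 0))
  expect_equal(convert_probability(q, 0.25, 1), p, tolerance = 1e-12)
})

test_that("zero hazards give the identity matrix and a frozen cohort", {
  cfg <- toy_chain_config(death_per_cycle = 0)
  M <- build_transition_matrix(cfg$transitions, cfg$states, 0, cfg)
  expect_equal(unname(M), diag(2), tolerance = 1e-15)
  tr <- run_cohort(cfg)
  expect_true(all(tr$occupancy[, "alive"] == 1000))
})

test_that("suicide excess multiplies the per-cycle death probability in depressed states only", {
  cfg <- gen_one(8)
  # per-cycle baseline death of exactly 0.01 in the active band
  p_annual <- 1 - 0.99^4
  cfg$transitions$baseline_mortality_annual <- data.frame(
    age_lo = 15, age_hi = 120, male = p_annual, female = p_annual)
  cfg$transitions$suicide_mortality_multiplier <- 1.5
  M <- build_transition_matrix(cfg$transitions, cfg$states, 0, cfg)
  expect_equal(M["depressed_treated", "deceased"], 0.015, tolerance = 1e-12)
  expect_equal(M["depressed_untreated", "deceased"], 0.015, tolerance = 1e-12)
  expect_equal(M["recovered_treated", "deceased"], 0.01, tolerance = 1e-12)
  expect_equal(M["recovered_untreated", "deceased"], 0.01, tolerance = 1e-12)
})

test_that("early retirement stops at age 50", {
  cfg <- gen_one(9)
  below <- build_transition_matrix(cfg$transitions, cfg$states, 0, cfg)
  expect_gt(below["recovered_untreated", "retired"], 0)

  cfg50 <- cfg
  cfg50$transitions$cohort_start_age <- 55
  above <- build_transition_matrix(cfg50$transitions, cfg50$states, 0, cfg50)
  nonret <- setdiff(cfg$states$name, "retired")
  expect_true(all(above[nonret, "retired"] == 0))
})

test_that("named transitions summing above 1 raise an infeasible-parameters error", {
  cfg <- gen_one(10)
  cfg$transitions$remission_untreated_12m <- 0.9999
  cfg$transitions$treatment_initiation_12m <- 0.9999
  err <- expect_error(build_transition_matrix(cfg$transitions, cfg$states, 0, cfg),
                      class = "depcohort_infeasible_error")
  expect_match(conditionMessage(err), "depressed_untreated")
})

test_that("every built matrix is row-stochastic (1000 random parameter draws)", {
  states <- default_states()
  set.seed(99)
  for (i in 1:1000) {
    tr <- list(
      remission_treated_12m = runif(1), remission_untreated_12m = runif(1),
      relapse_treated_12m = runif(1), relapse_untreated_12m = runif(1),
      treatment_initiation_12m = runif(1),
      baseline_mortality_annual = data.frame(
        age_lo = 15, age_hi = 120, male = runif(1, 0, 0.2), female = runif(1, 0, 0.2)),
      suicide_mortality_multiplier = runif(1, 1, 3),
      early_retirement_annual = runif(1, 0, 0.3),
      cohort_start_age = runif(1, 20, 70), sex_mix = runif(1)
    )
    cfg <- list(run = list(cycle_length = 0.25))
    M <- tryCatch(build_transition_matrix(tr, states, sample(0:19, 1), cfg),
                  depcohort_infeasible_error = function(e) NULL)
    if (is.null(M)) next  # feasibility is a separate, tested contract
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("toy death chain reproduces the closed-form survivor count", {
  cfg <- toy_chain_config(death_per_cycle = 0.1, horizon = 4L)
  tr <- run_cohort(cfg)
  expect_equal(tr$occupancy["4", "alive"], 1000 * 0.9^4, tolerance = 1e-12)
  expect_equal(nrow(tr$occupancy), 5)
  # conservation at every cycle
  expect_true(all(abs(rowSums(tr$occupancy) - 1000) < 1e-9))
})

test_that("trace_oracle matches direct products and the cycle loop", {
  cfg <- toy_chain_config(death_per_cycle = 0.1, horizon = 4L)
  M <- build_transition_matrix(cfg$transitions, cfg$states, 0, cfg)
  v0 <- c(1000, 0)
  expect_equal(trace_oracle(M, v0, 0), v0)
  expect_equal(trace_oracle(M, v0, 1), drop(v0 %*% M))
  tr <- run_cohort(cfg)
  expect_equal(unname(trace_oracle(M, v0, 4)), unname(tr$occupancy["4", ]),
               tolerance = 1e-10)
  expect_error(trace_oracle(matrix(1, 2, 3), c(1, 0), 1),
               class = "depcohort_domain_error")
})

test_that("cycle loop equals matrix-power oracle on time-homogeneous configs", {
  # start age 40 with a single 40-50 band: homogeneous below the cutoff
  fx <- get_fixture()
  for (cfg in fx$configs[c("abs_blue", "pres_white")]) {
    cfg$run$horizon <- 20L
    M <- build_transition_matrix(cfg$transitions, cfg$states, 0, cfg)
    v0 <- setNames(numeric(nrow(cfg$states)), cfg$states$name)
    v0[names(cfg$initial)] <- 1000 * cfg$initial
    tr <- run_cohort(cfg)
    for (t in 0:20)
      expect_equal(unname(trace_oracle(M, v0, t)), unname(tr$occupancy[t + 1, ]),
                   tolerance = 1e-10)
  }
  # and above the cutoff (no retirement, 50-60 band covers the horizon)
  cfg <- fx$configs$abs_blue
  cfg$transitions$cohort_start_age <- 55
  cfg$run$horizon <- 16L
  M <- build_transition_matrix(cfg$transitions, cfg$states, 0, cfg)
  v0 <- setNames(numeric(nrow(cfg$states)), cfg$states$name)
  v0[names(cfg$initial)] <- 1000 * cfg$initial
  tr <- run_cohort(cfg)
  for (t in 0:16)
    expect_equal(unname(trace_oracle(M, v0, t)), unname(tr$occupancy[t + 1, ]),
                 tolerance = 1e-10)
})

test_that("absorbing-state occupancy never decreases", {
  cfg <- gen_one(12)
  cfg$run$horizon <- 20L
  tr <- run_cohort(cfg)
  expect_true(all(diff(tr$occupancy[, "deceased"]) >= -1e-12))
  expect_true(all(diff(tr$occupancy[, "retired"]) >= -1e-12))
})
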
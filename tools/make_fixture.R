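#!/usr/bin/env Rscript
# Freezes the packaged reference fixture under inst/extdata/.
#
# Deterministic reference outcomes are computed here by the matrix-power
# oracle (trace_oracle) plus a standalone accumulation loop — NOT by
# run_cohort()/accumulate_outcomes() — so the shipped references are
# independent of the engine's cycle loop. The fixture quadruple is
# time-homogeneous by construction (start age 40, one mortality band
# covering 40-49, retirement cutoff never crossed), which makes the
# matrix-power oracle exact.
#
# Run from the repository root after installing the package:
#   Rscript tools/make_fixture.R

library(depcohort)

FIXTURE_SEED <- 2007L

qs <- generate_scenario_set(FIXTURE_SEED)

# ---- configs -------------------------------------------------------------
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
tmp <- tempfile(fileext = ".json")
cfg_out <- lapply(qs, function(cfg) {
  save_scenario(cfg, tmp)
  jsonlite::fromJSON(tmp, simplifyVector = FALSE)
})
jsonlite::write_json(cfg_out, "inst/extdata/fixture_configs.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# ---- deterministic references via the oracle path ------------------------
oracle_outcome <- function(cfg) {
  st <- cfg$states
  cl <- cfg$run$cycle_length
  Tn <- cfg$run$horizon
  N <- cfg$run$cohort_size
  r <- cfg$run$annual_discount_rate
  mult <- mean(cfg$costs$turnover_cost_multiplier_range)

  M <- build_transition_matrix(cfg$transitions, st, 0, cfg)
  # guard: the fixture must be time-homogeneous for the oracle to apply
  for (t in seq_len(Tn) - 1L)
    stopifnot(max(abs(build_transition_matrix(cfg$transitions, st, t, cfg) - M)) == 0)

  v0 <- setNames(numeric(nrow(st)), st$name)
  v0[names(cfg$initial)] <- N * cfg$initial

  cost_s <- sapply(seq_len(nrow(st)), function(i) c(
    lpt = lost_productive_time_cost(st[i, ], cfg$costs, cfg$scenario),
    turnover = expected_turnover_cost(st[i, ], cfg$costs, mult, cl),
    service = service_use_cost(st[i, ], cfg$costs, cl),
    antidepressant = antidepressant_cost(st[i, ], cfg$costs, cl)
  ))
  colnames(cost_s) <- st$name
  util <- setNames(numeric(nrow(st)), st$name)
  util[names(cfg$utilities)] <- cfg$utilities
  util["deceased"] <- 0

  acc <- c(lpt = 0, turnover = 0, service = 0, antidepressant = 0)
  qaly <- 0
  for (t in seq_len(Tn)) {
    vt <- trace_oracle(M, v0, t)
    d <- (1 + r)^(-t * cl)
    acc <- acc + d * as.vector(cost_s %*% vt)
    qaly <- qaly + d * sum(vt * util) * cl
  }
  acc <- acc / N
  list(scenario = cfg$scenario, occupation = cfg$occupation, horizon = Tn,
       cost_lpt = acc[["lpt"]], cost_turnover = acc[["turnover"]],
       cost_service = acc[["service"]], cost_antidepressant = acc[["antidepressant"]],
       cost_total = sum(acc), qalys = qaly / N)
}

reference <- lapply(qs, oracle_outcome)
jsonlite::write_json(reference, "inst/extdata/fixture_reference.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# ---- PSA regression freeze (seed 0, n = 1000) ----------------------------
psa_ref <- lapply(qs, function(cfg) {
  res <- run_psa(cfg, 1000L, seed = 0L)
  s <- res$summaries
  setNames(lapply(seq_len(nrow(s)), function(i)
    list(mean = s$mean[i], low = s$low[i], high = s$high[i])), s$outcome)
})
jsonlite::write_json(psa_ref, "inst/extdata/fixture_psa_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# sanity: engine agrees with the oracle references
for (nm in names(qs)) {
  eng <- accumulate_outcomes(run_cohort(qs[[nm]]), qs[[nm]])
  stopifnot(abs(eng$cost_total - reference[[nm]]$cost_total) < 1e-9,
            abs(eng$qalys - reference[[nm]]$qalys) < 1e-12)
}
cat("fixture frozen; engine/oracle agreement verified\n")
for (nm in names(qs))
  cat(sprintf("%-10s total %8.2f  qalys %.4f\n", nm,
              reference[[nm]]$cost_total, reference[[nm]]$qalys))
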
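---
title: "Modelling the costs and health outcomes of depression-related absenteeism and presenteeism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the costs and health outcomes of depression-related absenteeism and presenteeism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depcohort)
```

## The model

`depcohort` implements a state-transition Markov cohort model for
employed adults with major depression. A closed hypothetical cohort of
N = 1000 workers is distributed over a set of mutually exclusive health
states and redistributed every 3-month cycle by a row-stochastic
transition matrix. Two scenarios are compared as mutually exclusive
work-attendance patterns: **absenteeism** (depression-specific days
totally unable to work) and **presenteeism** (working while ill, zero
depression-specific absence days), each stratified by occupation
(blue vs white collar).

The default roster has six states: depression status (depressed /
recovered) crossed with treatment status (in treatment / not in
treatment), plus two absorbing states, *deceased* and *retired*. The
roster is configuration data: the engine reads the per-state flags
(`alive`, `depressed`, `in_treatment`, `absorbing`, `employed`) and
never hard-codes state names beyond the two absorbing conventions, so a
seventh state can be added in a scenario file without engine changes.
We deliberately keep the roster configurable because the published
description of this model class names seven states while only six are
identifiable from the accompanying text.

### Transitions

All transition inputs are 12-month probabilities converted to the
3-month cycle under a constant-hazard assumption,

$$p_{\Delta t} = 1 - (1-p_{T})^{\Delta t / T},$$

the standard conversion in cohort modelling. Remission (treated or
untreated, by the origin state's treatment flag) moves depressed →
recovered; relapse is the converse; treatment initiation moves
not-in-treatment → in-treatment. Mortality is an age-banded annual
all-cause table mixed over sex by the stratum's proportion female, and
is multiplied in depressed states by a suicide-excess factor ≥ 1 —
applied to the *per-cycle* probability, after period conversion. Early
retirement applies from employed states only while the cohort is
younger than 50.

Competing risks within a cycle are resolved **death first**: the
per-cycle death probability $q$ enters the deceased column unscaled,
every other named transition $p_i$ receives survivor mass
$(1-q)\,p_i$, and the self-transition takes the residual
$(1-q)(1-\sum_i p_i)$. Named transitions are never rescaled against
each other; if their sum exceeds 1 the parameter set is reported as
infeasible rather than silently renormalised. This ordering is a
modelling choice (the textual description of this model class does not
state one); it guarantees row sums of exactly 1 under any feasible
hazards and is covered by a property test over 1000 random parameter
draws.

The cohort is aged by a scalar `cohort_start_age` advancing 0.25
years/cycle (default 40), with a single cohort rather than sex-split
sub-cohorts: mortality is sex-weighted instead. Matrices are rebuilt
each cycle, but only the age-50 retirement cutoff and age-band
boundaries introduce time-dependence; configurations whose horizon
stays inside one band are exactly time-homogeneous, which is what makes
the matrix-power oracle (`trace_oracle()`, repeated squaring) an
independent exact check on the cycle loop.

### Costs and health outcomes

Four cost channels (2007 AUD, societal perspective) are attached to
states by their flags:

* **Lost productive time** — depression-specific absenteeism or
  presenteeism days per cycle × average daily wage; depressed,
  employed states only.
* **Job turnover** — per-cycle turnover probability (converted from the
  12-month 10.5% estimate) × a multiplier of annual salary (uniform
  0.75–1.5 in the PSA; deterministic runs use the midpoint 1.125);
  restricted to depressed-in-treatment employed states because the
  source estimate comes from treatment-seeking samples. A second,
  default-zero turnover probability attaches to employed non-depressed
  states purely so one-way sweeps can explore background turnover.
* **Service use** — annual contacts with GPs, psychologists,
  psychiatrists, mental-health nurses and alternative therapists,
  pro-rated to the cycle and priced at per-contact unit costs;
  in-treatment states only.
* **Antidepressants** — the 2-week use probability converted to the
  cycle (exponent 0.25/(2/52) = 6.5) × the 3-month SSRI script cost;
  in-treatment states only.

Health outcome is QALYs from AQoL-4D-style per-state utilities
(deceased fixed at 0; retired defaults to the recovered-untreated
utility since the source is silent on retiree quality of life).

Accrual timing: end-of-cycle occupancy earns the cycle's payoff,
cycle 0 earns nothing, and cycle *t* is discounted by
$(1+r)^{-t\,L}$ with $r = 3\%$/year and $L = 0.25$ years. A
half-cycle correction (mean of boundary occupancies) is available via
`run$half_cycle_correction` but off by default, since the modelled
source does not mention one. Totals are divided by the *initial* N —
"per employee with depression" — not by survivors. The total cost is
computed as the exact sum of the four channels; there is no separate
accumulation path that could drift from the components.

## Probabilistic sensitivity analysis

`run_psa()` samples every parameter listed in the config's `psa` block:
**beta** for probabilities and utilities, **gamma** for costs and day
counts, **uniform** where only a range is defensible (the turnover
multiplier, the suicide excess), `fixed` otherwise. Beta and gamma are
parameterised from (mean, se) by method of moments
($\nu = m(1-m)/se^2 - 1$; shape $=(m/se)^2$, scale $=se^2/m$); when a
source reports a 95% CI instead of an se, use $se = (hi-lo)/3.92$.
Each iteration reseeds deterministically from (seed, iteration), so
results are reproducible and independent of execution order; draws that
make a transition row infeasible are redrawn (≤ 10 times, then a hard
error) and counted. Summaries are means and equal-tailed 95% credible
intervals computed by **nearest rank** (no interpolation — deterministic
across platforms; an epsilon guards the rank ceiling against float
noise). The default of 1000 iterations is conventional; note the
cohort size N = 1000 is a different quantity.

Scenario comparison (`compare_scenarios()`, `cmd_compare()`) reports
mean differences, per-outcome interval overlap and the ICER. The two
scenarios use independent random streams by default; `paired = TRUE`
applies common random numbers for variance reduction.

One-way sensitivity (`one_way_sensitivity()`, `uniform_wage_sweep()`)
reruns the *deterministic* model per swept value — point estimates, not
nested PSAs — because the published sensitivity tables this mirrors
print single dollar figures per alternative value.

## The synthetic scenario generator

The survey-derived parameter tables behind the original model are not
available in machine-readable form, so `generate_scenario_set()` draws
complete, internally consistent scenario quadruples instead. It anchors
only to printed headline values — daily wages 170/215 AUD and salaries
44 252/55 595 AUD for blue/white collar (±20% jitter shared across
occupations within a draw, so the white-collar premium survives every
draw), 12-month turnover probability 10.5%, multiplier range 0.75–1.5,
3% discounting, N = 1000, 3-month cycles — and samples the rest from
ranges a practitioner would call plausible: 12-month remission 0.3–0.7
treated / 0.1–0.4 untreated (treated ≥ untreated enforced), relapse
0.05–0.3 / 0.1–0.5 (untreated ≥ treated), treatment initiation
0.2–0.5, utilities 0.45–0.70 depressed / 0.75–0.90 recovered, suicide
excess 1.3–2.3, annual early retirement 0.5–3%, and a fixed
Australian-plausible mortality table. Absenteeism reporters draw 12–25
lost days per cycle and presenteeism reporters 1–12 — a severity
gradient consistent with absentees being the sicker group — and the
initial Dirichlet weights put more of the absenteeism cohort in
depressed/in-treatment states. Each generated config carries a PSA
block whose means equal its own point values.

What the generator does **not** emulate: survey weighting and design
effects, parameter correlation (all PSA draws are independent),
severity stratification, seasonal or secular trends, and any real
difference in epidemiological parameters between occupations (only
income and sex mix differ). Passing tests therefore demonstrate the
*mechanics* — conservation, discounting, distributional sampling,
orderings driven by construction — not agreement with any particular
population's costs.

The packaged fixture (`packaged_fixture()`) freezes the quadruple at
seed 2007 together with reference outputs computed at freeze time by
the matrix-power oracle plus a standalone accumulation loop —
deliberately not by `run_cohort()`/`accumulate_outcomes()` — so the
regression test cannot inherit an engine bug. The fixture uses start
age 40 with a 40–49 mortality band, making it exactly time-homogeneous
over both 4- and 20-cycle horizons.

## Numerical choices and degenerate inputs

* Initial distributions must sum to 1 within 1e-9 with absorbing states
  empty; transition rows sum to 1 within 1e-12 by construction.
* Cohort propagation flags negative occupancy beyond −1e-9 as an
  internal error and clamps sub-epsilon negatives to 0.
* Ages outside the mortality table clamp to the nearest band.
* A state roster lacking a transition's target simply drops that hazard
  (e.g. a two-state toy chain has no recovered state to remit to).
* All-zero hazards give the identity matrix; a frozen cohort is valid.
* `validate_scenario()` returns violations as data (field, value,
  rule), so a driver can report all problems at once; only
  `load_scenario()` turns them into an error.

### Problem sizes used in the tests

The suite runs the full pipeline at the study conditions (N = 1000,
3-month cycles): 100 generated configurations over 20 cycles for the
conservation and monotonicity properties, 1000 random parameter draws
for row-stochasticity, 100 000 draws for the moment-fit Monte Carlo
checks, 50 000 draws for the analytic-quantile check on the credible
interval primitive, and the frozen 1000-iteration PSA regression per
stratum. The whole suite completes in well under a minute.

## Known limitations

* A cohort model cannot represent individual heterogeneity or history
  dependence (e.g. relapse risk rising with prior episodes); tunnel
  states are out of scope.
* The death-first competing-risk ordering and the accrual/discounting
  conventions are documented choices among several defensible ones;
  alternatives would change results by O(cycle-probability) factors.
* Turnover cost dominates total cost while resting on the weakest
  evidence; the wide multiplier range and the dedicated sweeps exist
  precisely to expose that sensitivity.
* Synthetic parameters are plausible, not estimated: absolute cost
  levels produced here characterise the generator, not any real
  workforce.
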
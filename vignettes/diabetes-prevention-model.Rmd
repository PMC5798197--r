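---
title: "A Markov cohort model of type 2 diabetes prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of type 2 diabetes prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevt2dm)
```

## The decision problem

Adults whose glycaemia is above normal but below the diagnostic threshold
for type 2 diabetes (T2DM) — *intermediate hyperglycaemia* — can be
identified by three different tests: impaired fasting glucose (IFG),
impaired glucose tolerance (IGT), or HbA1c in the at-risk range. These are
physiologically distinct populations with different prevalence, annual
risk of progression to T2DM, costs of care and utilities. Health systems
can offer such people a low-intensity ("pragmatic") group lifestyle
programme, an intensive one-to-one lifestyle programme, or metformin — or
nothing.

`prevt2dm` implements a cohort-level decision model that compares those
four strategies in each of the three cohorts (12 arms) over a lifetime
horizon, from a health-system perspective in 2015 GBP, and propagates
parameter uncertainty through every output.

## Model structure

The Markov chain has four clinical states: normoglycaemia (NGT),
intermediate hyperglycaemia (IH), T2DM and death. The cohort enters
entirely in IH at a single starting age (default 55, the midpoint of a
50–59 target group) and is propagated with annual cycles over a 50-year
horizon. Permitted transitions are IH → {T2DM, NGT, death}, NGT → {IH,
death}, T2DM → death; NGT cannot reach T2DM within one cycle, and T2DM is
never left except by death.

Because the annual cost of T2DM rises with time since diagnosis, T2DM is
expanded into 15 *tunnel states* indexed by years since onset (the 15th is
self-absorbing until death). A memoryless four-state chain cannot carry a
duration-dependent payoff; the tunnel expansion makes the cost ramp — a
linear rise from £1,179 in the first year to £2,939 in year 15, constant
thereafter — exactly representable.

Within a cycle, death is resolved first and the disease transitions share
the surviving mass (a standard competing-risk decomposition; the ordering
convention is a modelling choice, stated here because it is not uniquely
determined by annual transition probabilities). Background mortality
`q(age)` comes from a life table and is adjusted for the IH and T2DM
states through hazard ratios on the hazard scale,

$$ q' = 1 - (1 - q)^{\mathrm{HR}}, $$

which is exact for a constant within-cycle hazard. Interventions multiply
the IH → T2DM probability by a time-varying relative risk (RR), capped so
the probability never exceeds 1.

## Intervention profiles

| Strategy | Costs (GBP/year) | Incremental utility | RR schedule |
|---|---|---|---|
| Pragmatic lifestyle | 203.44, 80.02 (years 1–2) | 0.0189 | 0.74 in years 1–2, then 1 |
| Intensive lifestyle | 1225, 689, 671 (years 1–3) | 0.0189 | 0.63/0.55/0.71 (IFG/IGT/HbA1c) in years 1–3; 0.80/0.80/0.71 in years 4–10; then 1 |
| Metformin | 124.25 while in IH | 0.0031 | 0.82/0.82/0.62 through year 15 (IGT/IFG) or 10 (HbA1c); then 1 |

The pragmatic programme's effect is conservatively assumed to stop when
delivery stops; the intensive programme's effect attenuates after year 3
and ceases 10 years after it began; metformin's effect is held constant
for the longest published follow-up in each population. Metformin therapy
itself (cost and its small incremental utility) continues for as long as
the participant remains in IH.

Intervention costs and incremental utility accrue to the IH-occupying
fraction of the cohort, mirroring the explicit rule that metformin is
taken only while intermediate hyperglycaemia persists; a config switch
(`accrue_to_all`) instead accrues them to all alive states, for users who
prefer an intention-to-treat costing.

RR schedules are indexed by model year (the whole cohort enters IH at
t = 0), so mass that reverts to NGT and later relapses into IH during the
effect window also receives the RR. This is a deliberate cohort-level
simplification; resolving individual treatment histories would require
microsimulation, which is out of scope.

## Rewards and discounting

Each cycle contributes state costs (including the T2DM tunnel ramp),
intervention costs, optional unrelated healthcare costs for alive states
(a scenario), and state utilities plus the intervention's incremental
utility. Rewards use the cycle-start convention over cycles 0…49,
discounted at 3.5%/year by $(1.035)^{-t}$; a half-cycle (trapezoidal)
correction is available via `global_params(half_cycle = TRUE)` but is off
by default, matching the convention the deterministic checks in the test
suite are written against. Incidence and years lived with T2DM are
reported undiscounted.

## Parameters and their distributions

Every scalar input is a `param_spec`: a point estimate, a standard error
and a parametric family (`beta` for probabilities and utilities, `gamma`
for costs, `lognormal` for relative risks, `fixed` for quantities with no
published SE). Probabilistic sensitivity analysis fits each family by the
method of moments — `beta_from_moments()`, `gamma_from_moments()`,
`lognormal_from_moments()` — so the sampled mean and SD reproduce the
configured values. Relative-risk SEs are printed on the natural (ratio)
scale against natural-scale means, so they are moment-matched to a
lognormal on that scale rather than treated as SEs of log-RR.

Two deliberate choices:

* The T2DM cost ramp has a single published SE (£270) for the range
  £1,179–£2,939. PSA samples the year-15 endpoint from Gamma(2939, 270)
  and scales the year-1 endpoint proportionally, preserving the ramp's
  shape rather than inventing a second, uncorrelated distribution.
* Parameters are sampled independently. No correlation structure between
  inputs is published, so none is imposed; this is recorded as an open
  modelling question rather than silently parameterised.

### Imputed placeholders

Several inputs the model needs have no published values in the main
evidence tables: the mortality hazard ratios for IH and T2DM, the annual
reversion probability IH → NGT, the incidence NGT → IH, the cohort
starting age, the national 50–59 population and the total diabetes
budget. `default_imputed_params()` supplies documented,
order-of-magnitude-plausible placeholders (HR 1.2 and 1.9; reversion
0.05/year; NGT → IH 0.02/year; age 55; 7,000,000 people; £10bn/year),
every one flagged `source = "imputed"`. Loading a configuration warns
once, listing each imputed value, and run manifests record them. These
placeholders make the pipeline exercisable end-to-end; they claim no
fidelity to the unavailable source appendix, and any of them can be
overridden in the configuration file.

The background life table is likewise synthetic: a Gompertz–Makeham
hazard, $q(a) = 1 - \exp(-(A e^{ba} + c))$, with defaults
$A = 2.5\times10^{-5}$, $b = 0.095$, $c = 10^{-4}$ chosen to give a
realistic modern-mortality shape (q(55) ≈ 0.005) without reproducing any
national table. Users with a real life table supply a two-column CSV
(`age, qx`).

## Economic analysis

Per arm, the model reports discounted cost, discounted QALYs, cumulative
T2DM incidence (at 10 years and at the horizon) and undiscounted expected
years lived with T2DM. `frontier()` orders strategies by cost, removes
strictly dominated ones, then iteratively removes extendedly dominated
ones (a strategy whose ICER against its predecessor exceeds the next
strategy's ICER against that same predecessor) until ICERs strictly
increase; `cer_vs_reference()` reports each active strategy against no
intervention. Ties in cost and QALYs are merged with a warning — exact
ties have measure zero in practice and no published convention exists.
Frontiers are always computed from full-precision model outputs, never
from rounded report tables, because rounded incremental columns are not
internally consistent with the ICERs they imply.

`run_psa()` draws all non-fixed parameters per iteration (common random
parameters across all 12 arms), and `ceac()` turns the draws into
cost-effectiveness acceptability curves: the empirical fraction of
iterations in which each strategy has maximal net monetary benefit
(`nmb = wtp × QALYs − cost`), ties split equally. `ceac_pairwise()` gives
the probability a strategy beats a fixed comparator, the quantity usually
quoted as "probability cost-effective vs no intervention". The default
PSA size is 10,000 iterations with the seed recorded in every manifest;
the examples and tests here use 400–1,000 iterations, which keeps Monte
Carlo error on acceptability probabilities near one percentage point
while remaining fast.

One-way sensitivity analysis (`tornado_one_way()`) re-runs the
deterministic model with each parameter at ±10% and tabulates the
headline CER range. Named scenarios (`run_scenario()`) cover an extended
intervention-effect duration (default: to the full horizon, since the
exact extension is not published), ±20% intervention costs, inclusion of
unrelated healthcare costs (default £2,000/year per survivor), and a
WHO-criteria IFG definition — the last requires a user-supplied parameter
block, because no WHO-criteria values are bundled.

## Population scaling

The national projection assumes 50% of people with intermediate
hyperglycaemia are diagnosed and 50% of those offered a programme enrol.
Each arm's target population aggregates the disjoint diagnostic
categories: the IGT arm covers every category containing IGT; the IFG arm
covers isolated IFG and IFG+HbA1c; the HbA1c arm covers isolated HbA1c.
`budget_stream()` scales a per-person incremental discounted cost stream
to the enrolled population and expresses it as a share of the total
diabetes budget; `cases_prevented()` differences the cumulative incidence
curves. Percentage reductions in the population tables are diluted across
the arm's whole target population (non-enrolled members experience
no-intervention outcomes): a closed single cohort, with no births,
migration or rolling recruitment.

## What the synthetic inputs do and do not support

With placeholder mortality, reversion and population inputs, absolute
outputs (total costs, absolute incidence, national case counts) are
illustrative, not estimates for any real population. What the test suite
establishes is structural: mass conservation, agreement with matrix-power
and closed-form oracles, the published relative-risk schedule and cost
ramp reproduced cell-for-cell, moment recovery for every published
distribution, frontier correctness against brute-force enumeration, and
monotone responses to effect size and discounting. One qualitative
comparative ordering is *not* reproduced under the published main-text
parameters: in the HbA1c cohort, metformin (RR 0.62 through year 10, at
£124.25/year) outperforms the intensive programme (RR 0.71 over the same
window) on incidence and undercuts the pragmatic programme's CER, whereas
the published comparative tables order these the other way on the
strength of appendix-only parameters. The corresponding acceptance test
asserts the published ordering and is expected to fail on those two
HbA1c comparisons; the discrepancy is a property of the available inputs,
not of the implementation.

## Worked example

```{r example, eval = FALSE}
model <- replication_config()
results <- run_strategies(model)
results_table(results)

frontier(results[paste("IFG", c("NONE", "PRAGMATIC", "INTENSIVE",
                                "METFORMIN"), sep = ".")])

psa <- run_psa(model, 1000, seed = 1)
ceac(psa_cohort_draws(psa, "IFG"), wtp_grid = seq(0, 40000, 5000))
```

## Numerical conventions

* Conservation is asserted to 1e-10 per cycle; matrix rows are stochastic
  to 1e-12 by construction.
* Probabilities produced by RR multiplication are capped at 1; competing
  probabilities from one state that would exceed 1 after capping are an
  error naming the state, never silently renormalised.
* `perturb()` clips beta-family means at 1 with a warning (and zeroes the
  SE, since a beta cannot have mean 1 with positive variance).
* PSA draws are reproducible bit-for-bit from the seed; infeasible draws
  are resampled with the count reported.
* Model horizons in the test suite are 10–50 years, chosen so the full
  suite (including a 1,000-iteration PSA run twice for reproducibility)
  completes in a few minutes on one core.

## Limitations

Cohort-level simplifications (RR indexed by model time, no individual
treatment histories), no adverse events of metformin beyond its lower
incremental utility, no effects on non-diabetes disease, a single closed
cohort, and independence of sampled parameters. Continuous-glycaemia
microsimulation would relax the first two but needs richer data than the
published tables provide.
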
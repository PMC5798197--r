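# prevt2dm

Cost-effectiveness modelling of type 2 diabetes (T2DM) prevention
programmes for adults with intermediate hyperglycaemia — impaired fasting
glucose (IFG), impaired glucose tolerance (IGT), or HbA1c in the at-risk
range. The package is aimed at health economists and analysts who need a
transparent, fully scriptable alternative to spreadsheet or proprietary
decision-tree tools for this class of problem.

## The model

A Markov cohort model with annual cycles over a 50-year horizon compares
four strategies — no intervention, a pragmatic (low-intensity) lifestyle
programme, an intensive lifestyle programme, and metformin — in each of
the three cohorts (12 arms). States are normoglycaemia (NGT),
intermediate hyperglycaemia (IH), T2DM and death, with T2DM expanded into
15 tunnel states so its annual cost can ramp linearly from £1,179 (year 1
after onset) to £2,939 (year 15, 2015 GBP). Interventions act as
time-varying relative risks on the IH → T2DM transition, with
per-strategy effect windows; mortality is a life-table hazard adjusted per
state by `q' = 1 − (1 − q)^HR`. Costs and QALYs are discounted at
3.5%/year.

On top of the engine: discounted cost/QALY accumulation, cumulative
incidence and years lived with T2DM; cost-effectiveness ratios and an
ICER frontier with strict and extended dominance; net monetary benefit
(`wtp × QALYs − cost`) and cost-effectiveness acceptability curves from
probabilistic sensitivity analysis; one-way ±10% tornado analysis; named
scenario analyses; and an England-style population projection
(identification/enrolment cascade, cases prevented, budget-impact
streams).

Parameters the published evidence tables do not provide (mortality hazard
ratios, reversion probabilities, NGT → IH incidence, population
denominators, the background life table) ship as documented placeholders
flagged `source = "imputed"`; the methods vignette
(`vignettes/diabetes-prevention-model.Rmd`) explains each choice and what
the placeholders do and do not support.

## Worked example

```r
library(prevt2dm)

model <- replication_config()        # published values + placeholders
results <- run_strategies(model)     # all 12 cohort-by-strategy arms
results_table(results)
```

```
   cohort  strategy  cost qalys incidence_10y incidence_final mean_years_t2dm
1     IGT      NONE 19708 12.40        0.2945          0.4549           7.279
2     IGT PRAGMATIC 19697 12.47        0.2780          0.4425           6.949
3     IGT INTENSIVE 21060 12.56        0.2197          0.4011           5.990
4     IGT METFORMIN 20112 12.50        0.2495          0.4147           6.417
5     IFG      NONE 18262 12.61        0.2396          0.3873           6.066
6     IFG PRAGMATIC 18290 12.67        0.2258          0.3763           5.786
7     IFG INTENSIVE 19854 12.75        0.1835          0.3446           5.092
8     IFG METFORMIN 18793 12.70        0.2017          0.3507           5.313
...
```

Each row is one arm: lifetime discounted cost (GBP 2015) and QALYs per
participant, cumulative probability of developing T2DM by year 10 and by
the horizon, and undiscounted expected years lived with T2DM. In the IGT
cohort the pragmatic programme costs *less* than no intervention (averted
T2DM care more than offsets the £283 programme) while adding QALYs.

```r
frontier(results[paste("IFG", c("NONE", "PRAGMATIC", "INTENSIVE",
                                "METFORMIN"), sep = ".")])
```

```
   strategy  cost qalys    status inc_cost inc_qalys    icer
1      NONE 18262 12.61 reference       NA        NA      NA
2 PRAGMATIC 18290 12.67  frontier    28.16   0.05921   475.6
3 METFORMIN 18793 12.70  frontier   503.41   0.03281 15341.8
4 INTENSIVE 19854 12.75  frontier  1060.89   0.04187 25336.2
```

All four IFG strategies sit on the frontier here; each ICER is the extra
cost per extra QALY versus the previous frontier point. Probabilistic
analysis and acceptability:

```r
psa <- run_psa(model, 1000, seed = 1)
ceac_pairwise(psa_cohort_draws(psa, "IFG"), "PRAGMATIC", "NONE", 20000)
#   wtp probability
# 20000       0.974   # P(pragmatic beats nothing at £20,000/QALY)
```

A thin command-line front end over the same functions ships at
`inst/cli/prevt2dm.R` (`run`, `psa`, `tornado`, `scenario`, `population`,
`fixtures` subcommands); every output directory gets a JSON manifest with
the configuration hash, seed and the list of imputed placeholders in
force.

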
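Package: prevt2dm
Title: Markov Cohort Modelling of Type 2 Diabetes Prevention Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model for evaluating the
    cost-effectiveness of type 2 diabetes (T2DM) prevention in adults with
    intermediate hyperglycaemia (impaired fasting glucose, impaired glucose
    tolerance, or HbA1c in the at-risk range). Compares pragmatic and
    intensive lifestyle programmes and metformin against no intervention
    over a 50-year horizon with annual cycles and duration-dependent T2DM
    costs (tunnel states), producing discounted costs and QALYs, incidence
    and years lived with T2DM, cost-effectiveness frontiers with strict and
    extended dominance, probabilistic and one-way deterministic sensitivity
    analyses, cost-effectiveness acceptability curves, and population-scale
    budget-impact projections for an England-style screening and enrolment
    cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
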
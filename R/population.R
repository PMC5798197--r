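#' Population-level (budget impact) settings
#'
#' Prevalence of each intermediate-hyperglycaemia category in the 50-59
#' age group, the identification/enrolment cascade, and the population
#' denominators used to scale per-person results to an England-style
#' national programme. The seven prevalence categories are pairwise
#' disjoint. The population count and total diabetes budget are documented
#' placeholders (the underlying national statistics are not printed in the
#' evidence tables).
#'
#' @param population_5059 Number of 50-59 year-olds (placeholder default
#'   7,000,000).
#' @param prevalence Named vector of the seven disjoint category
#'   prevalences (proportions).
#' @param p_identified Probability a person with intermediate
#'   hyperglycaemia is diagnosed (0.5, the national costing-template
#'   assumption).
#' @param p_enrol Probability a person offered an intervention enrols
#'   (0.5).
#' @param total_diabetes_budget Total annual diabetes expenditure, GBP
#'   (placeholder default 1e10).
#' @param health_check_coverage Reported national health-check coverage
#'   interval in the 50-59 age group (metadata only; not used in
#'   computation).
#' @return A list of class `population_config`.
#' @export
population_config <- function(
    population_5059 = 7e6,
    prevalence = c(ifg_isolated = 0.1276, ifg_igt = 0.0149,
                   ifg_hba1c = 0.0661, ifg_igt_hba1c = 0.0106,
                   igt_isolated = 0.0750, igt_hba1c = 0.0331,
                   hba1c_isolated = 0.0753),
    p_identified = 0.5, p_enrol = 0.5,
    total_diabetes_budget = 1e10,
    health_check_coverage = c(0.137, 0.224)) {
  prevalence <- unlist(prevalence)
  need <- c("ifg_isolated", "ifg_igt", "ifg_hba1c", "ifg_igt_hba1c",
            "igt_isolated", "igt_hba1c", "hba1c_isolated")
  miss <- setdiff(need, names(prevalence))
  if (length(miss)) {
    stop(sprintf("prevalence is missing categories: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(prevalence < 0 | prevalence > 1) || sum(prevalence) > 1) {
    stop("prevalence categories must lie in [0, 1] and sum to <= 1",
         call. = FALSE)
  }
  for (p in c(p_identified, p_enrol)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("cascade probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(population_5059 = population_5059,
         prevalence = prevalence[need],
         p_identified = p_identified, p_enrol = p_enrol,
         total_diabetes_budget = total_diabetes_budget,
         health_check_coverage = unlist(health_check_coverage)),
    class = "population_config"
  )
}

#' Prevalence of a model arm's target population
#'
#' Each model arm represents everyone carrying that diagnosis, alone or in
#' combination: the IGT arm covers isolated IGT, IFG+IGT, IGT+HbA1c and the
#' triple category; the IFG arm covers isolated IFG and IFG+HbA1c (its
#' IGT-overlapping categories are counted in the IGT arm); the HbA1c arm
#' covers isolated HbA1c only.
#'
#' @param cohort One of `"IGT"`, `"IFG"`, `"HBA1C"`.
#' @param config A [population_config()].
#' @return Proportion of the population in the arm.
#' @export
arm_prevalence <- function(cohort, config) {
  stopifnot(inherits(config, "population_config"))
  cohort <- match.arg(cohort, COHORTS)
  pr <- config$prevalence
  switch(cohort,
    IGT = sum(pr[c("igt_isolated", "ifg_igt", "igt_hba1c",
                   "ifg_igt_hba1c")]),
    IFG = sum(pr[c("ifg_isolated", "ifg_hba1c")]),
    HBA1C = pr[["hba1c_isolated"]]
  )
}

#' Number of programme participants after the identification cascade
#'
#' `population * arm prevalence * P(identified) * P(enrol)`.
#'
#' @inheritParams arm_prevalence
#' @return Expected participant count (not rounded).
#' @export
cascade_size <- function(cohort, config) {
  stopifnot(inherits(config, "population_config"))
  config$population_5059 * arm_prevalence(cohort, config) *
    config$p_identified * config$p_enrol
}

#' Population budget-impact streams
#'
#' Scales a per-person incremental discounted cost stream to the enrolled
#' population and expresses each annual amount as a percentage of the total
#' diabetes budget.
#'
#' @param per_person Numeric vector: per-cycle discounted incremental cost
#'   versus no intervention (GBP per participant).
#' @param n Participant count (e.g. [cascade_size()]).
#' @param config A [population_config()].
#' @return Data frame with columns `year`, `annual`, `cumulative`,
#'   `pct_budget` (`NA` with a warning if the configured budget is zero).
#' @export
budget_stream <- function(per_person, n, config) {
  stopifnot(inherits(config, "population_config"), is.numeric(per_person),
            n >= 0)
  annual <- n * per_person
  if (config$total_diabetes_budget > 0) {
    pct <- 100 * annual / config$total_diabetes_budget
  } else {
    warning("total_diabetes_budget is zero; budget percentages undefined",
            call. = FALSE)
    pct <- rep(NA_real_, length(annual))
  }
  data.frame(year = seq_along(per_person), annual = annual,
             cumulative = cumsum(annual), pct_budget = pct)
}

#' Incident T2DM cases prevented by an intervention
#'
#' Compares cumulative 50-year (end-of-horizon) T2DM incidence between an
#' intervention arm and its no-intervention comparator, scaled to `n`
#' participants.
#'
#' @param result_intervention,result_none [accumulate()] results for the
#'   same cohort.
#' @param n Participant count.
#' @return List with `cases` (expected incident cases prevented) and
#'   `pct_reduction` (relative reduction in cumulative incidence, percent).
#' @export
cases_prevented <- function(result_intervention, result_none, n) {
  stopifnot(inherits(result_intervention, "strategy_result"),
            inherits(result_none, "strategy_result"))
  if (!identical(result_intervention$cohort, result_none$cohort)) {
    stop("results come from different cohorts", call. = FALSE)
  }
  h <- length(result_none$cum_incidence)
  ci_none <- result_none$cum_incidence[h]
  ci_int <- result_intervention$cum_incidence[h]
  pct <- if (ci_none > 0) 100 * (ci_none - ci_int) / ci_none else 0
  list(cases = n * (ci_none - ci_int), pct_reduction = pct)
}
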
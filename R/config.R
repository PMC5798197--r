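COHORTS <- c("IGT", "IFG", "HBA1C")
STRATEGIES <- c("NONE", "PRAGMATIC", "INTENSIVE", "METFORMIN")

# registry keys that must be present for the model to run
REQUIRED_PARAMS <- c(
  "cost_state_ngt", "cost_state_ih_igt", "cost_state_ih_ifg",
  "cost_state_ih_hba1c", "cost_t2dm_year1", "cost_t2dm_year15",
  "util_ngt", "util_ih_igt", "util_ih_ifg", "util_ih_hba1c", "util_t2dm",
  "p_t2dm_igt", "p_t2dm_ifg", "p_t2dm_hba1c",
  "p_revert_igt", "p_revert_ifg", "p_revert_hba1c", "p_ngt_to_ih",
  "hr_death_ih", "hr_death_t2dm",
  "util_incr_lifestyle", "util_incr_metformin",
  "rr_prag_during_igt", "rr_prag_during_ifg", "rr_prag_during_hba1c",
  "rr_int_during_igt", "rr_int_during_ifg", "rr_int_during_hba1c",
  "rr_int_post_igt", "rr_int_post_ifg", "rr_int_post_hba1c",
  "rr_met_igt", "rr_met_ifg", "rr_met_hba1c",
  "cost_prag_y1", "cost_prag_y2",
  "cost_int_y1", "cost_int_y2", "cost_int_y3",
  "cost_met_annual"
)

#' Published model parameters
#'
#' The registry of parameters printed in the evidence tables: state costs
#' (GBP, 2015 prices) and utilities, annual T2DM incidence per cohort,
#' intervention costs, incremental utilities, and the relative-risk
#' schedule values, each with the standard error and parametric family used
#' for probabilistic sensitivity analysis.
#'
#' The duration-dependent T2DM cost is parameterised by its two ramp
#' endpoints: the year-1 cost (GBP 1,179) and the year-15 cost (GBP 2,939).
#' The single printed SE (GBP 270) attaches to the year-15 endpoint; when
#' that endpoint is sampled, the year-1 endpoint is scaled proportionally
#' so the ramp keeps its shape (see [assemble_arm()]).
#'
#' @return Named list of [param_spec()] objects.
#' @export
published_params <- function() {
  p <- list(
    # annual cost of care per health state (GBP 2015)
    param_spec("cost_state_ngt", 773, 102.63, "gamma"),
    param_spec("cost_state_ih_igt", 946, 101.52, "gamma"),
    param_spec("cost_state_ih_ifg", 869, 104.56, "gamma"),
    param_spec("cost_state_ih_hba1c", 869, 104.56, "gamma"),
    param_spec("cost_t2dm_year1", 1179, 0, "fixed"),
    param_spec("cost_t2dm_year15", 2939, 270, "gamma"),
    # state utilities (QALY/year)
    param_spec("util_ngt", 0.768, 0.10, "beta"),
    param_spec("util_ih_igt", 0.746, 0.10, "beta"),
    param_spec("util_ih_ifg", 0.759, 0.11, "beta"),
    param_spec("util_ih_hba1c", 0.759, 0.11, "beta"),
    param_spec("util_t2dm", 0.738, 0.12, "beta"),
    # annual probability of progression IH -> T2DM
    param_spec("p_t2dm_igt", 0.0454, 0.004, "beta"),
    param_spec("p_t2dm_ifg", 0.0355, 0.006, "beta"),
    param_spec("p_t2dm_hba1c", 0.0356, 0.017, "beta"),
    # incremental utility while on an intervention
    param_spec("util_incr_lifestyle", 0.0189, 0.001, "beta"),
    param_spec("util_incr_metformin", 0.0031, 0.002, "beta"),
    # relative risks of developing T2DM (natural/ratio scale)
    param_spec("rr_prag_during_igt", 0.74, 0.11, "lognormal"),
    param_spec("rr_prag_during_ifg", 0.74, 0.11, "lognormal"),
    param_spec("rr_prag_during_hba1c", 0.74, 0.11, "lognormal"),
    param_spec("rr_int_during_igt", 0.55, 0.07, "lognormal"),
    param_spec("rr_int_during_ifg", 0.63, 0.10, "lognormal"),
    param_spec("rr_int_during_hba1c", 0.71, 0.10, "lognormal"),
    param_spec("rr_int_post_igt", 0.80, 0.06, "lognormal"),
    param_spec("rr_int_post_ifg", 0.80, 0.06, "lognormal"),
    param_spec("rr_int_post_hba1c", 0.71, 0.10, "lognormal"),
    param_spec("rr_met_igt", 0.82, 0.05, "lognormal"),
    param_spec("rr_met_ifg", 0.82, 0.05, "lognormal"),
    param_spec("rr_met_hba1c", 0.62, 0.10, "lognormal"),
    # programme costs (GBP 2015; no SE printed, held fixed in PSA)
    param_spec("cost_prag_y1", 203.44),
    param_spec("cost_prag_y2", 80.02),
    param_spec("cost_int_y1", 1225),
    param_spec("cost_int_y2", 689),
    param_spec("cost_int_y3", 671),
    param_spec("cost_met_annual", 124.25)
  )
  stats::setNames(p, vapply(p, function(s) s$name, character(1)))
}

#' Global model settings
#'
#' @param discount_rate Annual discount rate for costs and QALYs.
#' @param horizon_years Number of annual cycles.
#' @param wtp_threshold Willingness-to-pay threshold (GBP/QALY).
#' @param start_age Cohort age at model entry (placeholder; midpoint of the
#'   50-59 target group).
#' @param price_year Currency price year.
#' @param unrelated_annual_cost Annual non-diabetes healthcare cost applied
#'   to every alive state (0 in the base case; used in scenario analysis).
#' @param accrue_to_all If `TRUE`, intervention costs and incremental
#'   utility accrue to all alive states during the programme rather than
#'   only to the intermediate-hyperglycaemia state.
#' @param half_cycle If `TRUE`, rewards use a half-cycle (trapezoidal)
#'   correction; the default is the cycle-start convention.
#' @return A list of class `t2dm_globals`.
#' @export
global_params <- function(discount_rate = 0.035, horizon_years = 50,
                          wtp_threshold = 20000, start_age = 55,
                          price_year = 2015, unrelated_annual_cost = 0,
                          accrue_to_all = FALSE, half_cycle = FALSE) {
  if (!is.finite(discount_rate) || discount_rate < 0 || discount_rate >= 1) {
    stop("'discount_rate' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(horizon_years) || horizon_years < 1) {
    stop("'horizon_years' must be >= 1", call. = FALSE)
  }
  if (unrelated_annual_cost < 0) {
    stop("'unrelated_annual_cost' must be >= 0", call. = FALSE)
  }
  structure(
    list(discount_rate = discount_rate,
         horizon_years = as.integer(horizon_years),
         wtp_threshold = wtp_threshold,
         start_age = start_age,
         price_year = price_year,
         unrelated_annual_cost = unrelated_annual_cost,
         accrue_to_all = isTRUE(accrue_to_all),
         half_cycle = isTRUE(half_cycle)),
    class = "t2dm_globals"
  )
}

#' Relative-risk schedule boundaries by strategy
#'
#' Model years over which each intervention's relative risk of progression
#' applies: the pragmatic programme's effect lasts only for its 2 delivery
#' years; the intensive programme's in-programme effect covers years 1-3
#' with an attenuated effect up to 7 years post-intervention (through model
#' year 10); metformin's effect is constant through year 15 for IGT/IFG and
#' year 10 for HbA1c-identified participants, reflecting the longest
#' published follow-up in each population.
#'
#' @return Nested list used by [assemble_arm()] and modified by
#'   [run_scenario()] for the extended-effect scenario.
#' @export
default_rr_schedule <- function() {
  list(
    PRAGMATIC = list(during_end = 2, cease = 2),
    INTENSIVE = list(during_end = 3, cease = 10),
    METFORMIN = list(cease_by_cohort = c(IGT = 15, IFG = 15, HBA1C = 10))
  )
}

#' Construct a full model specification
#'
#' Bundles the parameter registry, global settings, relative-risk schedule,
#' background life table and population settings into one object from which
#' the 12 cohort-by-strategy arm configurations are assembled.
#'
#' @param params Named list of [param_spec()] objects; must contain every
#'   key the engine needs (see the error message on omission).
#' @param globals A [global_params()] object.
#' @param life_table Data frame with columns `age` and `qx` (annual
#'   probability of death).
#' @param population A [population_config()] object.
#' @param schedule A [default_rr_schedule()]-shaped list.
#' @return An object of class `t2dm_model`.
#' @export
t2dm_model <- function(params, globals = global_params(),
                       life_table = make_life_table(),
                       population = population_config(),
                       schedule = default_rr_schedule()) {
  validate_params(params)
  validate_life_table(life_table, globals)
  structure(
    list(params = params, globals = globals, life_table = life_table,
         population = population, schedule = schedule),
    class = "t2dm_model"
  )
}

validate_params <- function(params) {
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    stop("parameter registry must be a named list", call. = FALSE)
  }
  missing <- setdiff(REQUIRED_PARAMS, names(params))
  if (length(missing)) {
    stop(sprintf("configuration is missing required parameter(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ok <- vapply(params, inherits, logical(1), what = "param_spec")
  if (!all(ok)) {
    stop(sprintf("not a param_spec: %s",
                 paste(names(params)[!ok], collapse = ", ")), call. = FALSE)
  }
  invisible(params)
}

validate_life_table <- function(life_table, globals) {
  stopifnot(is.data.frame(life_table),
            all(c("age", "qx") %in% names(life_table)))
  if (any(life_table$qx < 0 | life_table$qx > 1)) {
    stop("life table death probabilities must lie in [0, 1]", call. = FALSE)
  }
  needed <- globals$start_age + seq_len(globals$horizon_years) - 1
  if (!all(needed %in% life_table$age)) {
    stop(sprintf("life table must cover ages %d-%d",
                 min(needed), max(needed)), call. = FALSE)
  }
  invisible(life_table)
}

#' Assemble one cohort-by-strategy arm configuration
#'
#' Resolves the parameter registry into the numeric values one model arm
#' needs: state payoffs, transition parameters, the intervention profile
#' (costs, incremental utility, relative-risk schedule) and globals. By
#' default the registry means are used (deterministic model); `values`
#' overrides them with, e.g., one PSA draw.
#'
#' When the year-15 T2DM cost endpoint is sampled away from its configured
#' mean, the year-1 endpoint is scaled by the same factor so the cost ramp
#' keeps its shape.
#'
#' @param model A [t2dm_model()].
#' @param cohort One of `"IGT"`, `"IFG"`, `"HBA1C"`.
#' @param strategy One of `"NONE"`, `"PRAGMATIC"`, `"INTENSIVE"`,
#'   `"METFORMIN"`.
#' @param values Optional named numeric vector overriding registry means.
#' @return An object of class `t2dm_arm`.
#' @export
assemble_arm <- function(model, cohort, strategy, values = NULL) {
  stopifnot(inherits(model, "t2dm_model"))
  cohort <- match.arg(cohort, COHORTS)
  strategy <- match.arg(strategy, STRATEGIES)
  v <- param_means(model$params)
  if (!is.null(values)) {
    v[names(values)] <- values
  }
  co <- tolower(cohort)
  ramp_scale <- v[["cost_t2dm_year15"]] / model$params$cost_t2dm_year15$mean
  payoffs <- list(
    cost_ngt = v[["cost_state_ngt"]],
    cost_ih = v[[paste0("cost_state_ih_", co)]],
    cost_t2dm_y1 = v[["cost_t2dm_year1"]] * ramp_scale,
    cost_t2dm_y15 = v[["cost_t2dm_year15"]],
    util_ngt = v[["util_ngt"]],
    util_ih = v[[paste0("util_ih_", co)]],
    util_t2dm = v[["util_t2dm"]]
  )
  transitions <- list(
    p_ih_to_t2dm = v[[paste0("p_t2dm_", co)]],
    p_ih_to_ngt = v[[paste0("p_revert_", co)]],
    p_ngt_to_ih = v[["p_ngt_to_ih"]],
    hr_death_ih = v[["hr_death_ih"]],
    hr_death_t2dm = v[["hr_death_t2dm"]]
  )
  sched <- model$schedule
  intervention <- switch(strategy,
    NONE = NULL,
    PRAGMATIC = list(
      name = "PRAGMATIC",
      annual_costs = c(v[["cost_prag_y1"]], v[["cost_prag_y2"]]),
      duration_years = 2,
      incremental_utility = v[["util_incr_lifestyle"]],
      rr_during = v[[paste0("rr_prag_during_", co)]],
      rr_post = 1,
      rr_during_end = sched$PRAGMATIC$during_end,
      rr_cease_year = sched$PRAGMATIC$cease
    ),
    INTENSIVE = list(
      name = "INTENSIVE",
      annual_costs = c(v[["cost_int_y1"]], v[["cost_int_y2"]],
                       v[["cost_int_y3"]]),
      duration_years = 3,
      incremental_utility = v[["util_incr_lifestyle"]],
      rr_during = v[[paste0("rr_int_during_", co)]],
      rr_post = v[[paste0("rr_int_post_", co)]],
      rr_during_end = sched$INTENSIVE$during_end,
      rr_cease_year = sched$INTENSIVE$cease
    ),
    METFORMIN = list(
      name = "METFORMIN",
      annual_costs = v[["cost_met_annual"]],
      duration_years = Inf,  # continued for as long as the participant is IH
      incremental_utility = v[["util_incr_metformin"]],
      rr_during = v[[paste0("rr_met_", co)]],
      rr_post = 1,
      rr_during_end = sched$METFORMIN$cease_by_cohort[[cohort]],
      rr_cease_year = sched$METFORMIN$cease_by_cohort[[cohort]]
    )
  )
  validate_arm(structure(
    list(cohort = cohort, strategy = strategy, payoffs = payoffs,
         transitions = transitions, intervention = intervention,
         globals = model$globals, life_table = model$life_table),
    class = "t2dm_arm"
  ))
}

validate_arm <- function(arm) {
  p <- arm$payoffs
  tr <- arm$transitions
  if (any(unlist(p[c("cost_ngt", "cost_ih", "cost_t2dm_y1",
                     "cost_t2dm_y15")]) < 0)) {
    stop("state costs must be >= 0", call. = FALSE)
  }
  if (p$cost_t2dm_y15 < p$cost_t2dm_y1) {
    stop("T2DM cost ramp end must be >= ramp start", call. = FALSE)
  }
  utils_ <- unlist(p[c("util_ngt", "util_ih", "util_t2dm")])
  if (any(utils_ < 0 | utils_ > 1)) {
    stop("state utilities must lie in [0, 1]", call. = FALSE)
  }
  probs <- unlist(tr[c("p_ih_to_t2dm", "p_ih_to_ngt", "p_ngt_to_ih")])
  if (any(probs < 0 | probs > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (tr$hr_death_ih <= 0 || tr$hr_death_t2dm <= 0) {
    stop("mortality hazard ratios must be > 0", call. = FALSE)
  }
  iv <- arm$intervention
  if (!is.null(iv)) {
    if (iv$rr_during <= 0 || iv$rr_post <= 0) {
      stop("relative risks must be > 0", call. = FALSE)
    }
    if (is.finite(iv$duration_years) &&
        length(iv$annual_costs) != iv$duration_years) {
      stop("intervention annual_costs length must equal duration_years",
           call. = FALSE)
    }
    if (iv$rr_cease_year < min(iv$duration_years, iv$rr_during_end)) {
      stop("rr_cease_year must not precede the in-programme effect window",
           call. = FALSE)
    }
  }
  arm
}

#' Assemble all 12 cohort-by-strategy arms
#'
#' @inheritParams assemble_arm
#' @return Named list of [assemble_arm()] results, names like
#'   `"IGT.PRAGMATIC"`.
#' @export
build_arms <- function(model, values = NULL) {
  grid <- expand.grid(strategy = STRATEGIES, cohort = COHORTS,
                      stringsAsFactors = FALSE)
  arms <- Map(function(co, st) assemble_arm(model, co, st, values),
              grid$cohort, grid$strategy)
  stats::setNames(arms, paste(grid$cohort, grid$strategy, sep = "."))
}

#' Write a model specification to JSON
#'
#' Serialises the parameter registry, globals, life table, population
#' settings and relative-risk schedule. The file round-trips losslessly
#' through [load_config()].
#'
#' @param model A [t2dm_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(model, path) {
  stopifnot(inherits(model, "t2dm_model"))
  obj <- list(
    params = lapply(model$params, function(s) {
      list(name = s$name, mean = s$mean, se = s$se, family = s$family,
           source = s$source)
    }),
    globals = unclass(model$globals),
    life_table = list(age = model$life_table$age, qx = model$life_table$qx),
    population = local({
      p <- unclass(model$population)
      p$prevalence <- as.list(p$prevalence)  # keep category names in JSON
      p
    }),
    schedule = local({
      s <- model$schedule
      s$METFORMIN$cease_by_cohort <- as.list(s$METFORMIN$cease_by_cohort)
      s
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load and validate a model specification from JSON
#'
#' Rebuilds a [t2dm_model()] from a file written by [write_config()],
#' re-validating every parameter invariant. One warning is emitted listing
#' all parameters whose `source` is `"imputed"`, so placeholder values are
#' visible in every run.
#'
#' @param path JSON file path.
#' @return A [t2dm_model()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$params)) {
    stop("config is missing the 'params' block", call. = FALSE)
  }
  params <- lapply(obj$params, function(s) {
    need <- c("name", "mean", "se", "family", "source")
    miss <- setdiff(need, names(s))
    if (length(miss)) {
      stop(sprintf("parameter entry missing field(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    param_spec(s$name, s$mean, s$se, s$family, s$source)
  })
  names(params) <- vapply(params, function(s) s$name, character(1))
  g <- obj$globals
  globals <- global_params(
    discount_rate = g$discount_rate, horizon_years = g$horizon_years,
    wtp_threshold = g$wtp_threshold, start_age = g$start_age,
    price_year = g$price_year,
    unrelated_annual_cost = g$unrelated_annual_cost,
    accrue_to_all = g$accrue_to_all, half_cycle = g$half_cycle
  )
  life_table <- data.frame(age = unlist(obj$life_table$age),
                           qx = unlist(obj$life_table$qx))
  pop <- do.call(population_config, obj$population)
  schedule <- obj$schedule
  schedule$METFORMIN$cease_by_cohort <-
    unlist(schedule$METFORMIN$cease_by_cohort)
  model <- t2dm_model(params, globals, life_table, pop, schedule)
  imp <- imputed_names(params)
  if (length(imp)) {
    warning(sprintf(
      "config uses imputed placeholder values (not from the published tables): %s",
      paste(imp, collapse = ", ")), call. = FALSE)
  }
  model
}

#' Multiply one parameter by a factor
#'
#' Returns a copy of the model with a single registry parameter's point
#' estimate multiplied by `factor` (the one-way sensitivity-analysis
#' primitive). Probability and utility parameters (beta family) are clipped
#' at 1 with a warning; a clipped beta parameter's SE is set to 0 because a
#' beta distribution cannot have mean 1 with positive variance.
#'
#' @param model A [t2dm_model()].
#' @param param Registry parameter name.
#' @param factor Positive multiplier.
#' @return A modified copy of `model`; the input is unchanged.
#' @export
perturb <- function(model, param, factor) {
  stopifnot(inherits(model, "t2dm_model"), is.finite(factor), factor > 0)
  if (!param %in% names(model$params)) {
    stop(sprintf("unknown parameter: '%s'", param), call. = FALSE)
  }
  spec <- model$params[[param]]
  new_mean <- spec$mean * factor
  new_se <- spec$se
  if (spec$family == "beta" && new_mean > 1) {
    warning(sprintf("'%s': perturbed value %g clipped to 1", param, new_mean),
            call. = FALSE)
    new_mean <- 1
    new_se <- 0
  }
  model$params[[param]] <- param_spec(spec$name, new_mean, new_se,
                                      spec$family, spec$source)
  model
}
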
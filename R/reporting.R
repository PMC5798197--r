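result_of <- function(results, cohort, strategy) {
  key <- paste(cohort, strategy, sep = ".")
  r <- results[[key]]
  if (is.null(r)) {
    stop(sprintf("missing arm result: %s", key), call. = FALSE)
  }
  r
}

#' Individual-participant result tables
#'
#' Builds the three headline tables for individual participants from a
#' full 12-arm result set:
#' \describe{
#'   \item{`costs`}{Total discounted cost, total discounted QALYs,
#'     cumulative T2DM incidence at the end of the horizon (the share of
#'     entrants who ever developed T2DM) and expected years lived with
#'     T2DM, per arm.}
#'   \item{`incidence`}{10-year and end-of-horizon cumulative incidence per
#'     arm, with relative risk reductions versus no intervention.}
#'   \item{`icers`}{Per cohort, the dominance-aware ICER frontier together
#'     with the cost-effectiveness ratio of every active strategy versus no
#'     intervention, and (when PSA draws are supplied) the probability of
#'     cost-effectiveness at the willingness-to-pay threshold, jointly and
#'     versus no intervention.}
#' }
#' Incremental columns are `NA` for the no-intervention reference row.
#' Every cell is recomputed from the result objects; nothing is read back
#' from rounded output.
#'
#' @param results Named list of all 12 `strategy_result`s (names like
#'   `"IGT.PRAGMATIC"`), e.g. from [run_strategies()].
#' @param psa Optional [run_psa()] object for acceptability columns.
#' @param wtp Willingness-to-pay threshold for acceptability columns.
#' @return List of data frames `costs`, `incidence`, `icers`.
#' @export
report_individual <- function(results, psa = NULL, wtp = 20000) {
  for (co in COHORTS) {
    for (st in STRATEGIES) result_of(results, co, st)  # completeness
  }
  costs <- do.call(rbind, lapply(COHORTS, function(co) {
    do.call(rbind, lapply(STRATEGIES, function(st) {
      r <- result_of(results, co, st)
      data.frame(cohort = co, strategy = st, total_cost = r$cost,
                 total_qalys = r$qalys,
                 t2dm_prevalence_final = r$incidence_final,
                 years_with_t2dm = r$mean_years_t2dm)
    }))
  }))
  incidence <- do.call(rbind, lapply(COHORTS, function(co) {
    ref <- result_of(results, co, "NONE")
    do.call(rbind, lapply(STRATEGIES, function(st) {
      r <- result_of(results, co, st)
      rrr <- function(x, x0) if (x0 > 0) 1 - x / x0 else NA_real_
      data.frame(cohort = co, strategy = st,
                 incidence_10y = r$incidence_10y,
                 incidence_final = r$incidence_final,
                 rrr_10y = if (st == "NONE") NA_real_
                           else rrr(r$incidence_10y, ref$incidence_10y),
                 rrr_final = if (st == "NONE") NA_real_
                             else rrr(r$incidence_final, ref$incidence_final))
    }))
  }))
  icers <- do.call(rbind, lapply(COHORTS, function(co) {
    arm_results <- lapply(STRATEGIES, function(st) result_of(results, co, st))
    names(arm_results) <- STRATEGIES
    fr <- frontier(arm_results)
    ref <- arm_results$NONE
    fr$cer_vs_none <- NA_real_
    fr$cost_vs_none <- NA_real_
    fr$qalys_vs_none <- NA_real_
    for (i in seq_len(nrow(fr))) {
      st <- fr$strategy[i]
      if (st != "NONE") {
        cv <- cer_vs_reference(arm_results[[st]], ref)
        fr$cer_vs_none[i] <- cv$cer
        fr$cost_vs_none[i] <- cv$delta_cost
        fr$qalys_vs_none[i] <- cv$delta_qalys
      }
    }
    if (!is.null(psa)) {
      draws <- psa_cohort_draws(psa, co)
      joint <- ceac(draws, wtp)
      fr$p_ce_joint <- joint$probability[match(fr$strategy, joint$strategy)]
      fr$p_ce_vs_none <- vapply(fr$strategy, function(st) {
        if (st == "NONE") return(NA_real_)
        ceac_pairwise(draws, st, "NONE", wtp)$probability
      }, numeric(1))
    }
    cbind(data.frame(cohort = co), fr)
  }))
  rownames(costs) <- rownames(incidence) <- rownames(icers) <- NULL
  list(costs = costs, incidence = incidence, icers = icers)
}

#' Population-level result tables
#'
#' Scales per-person results to the configured population through the
#' identification/enrolment cascade. Returns the national outcomes table
#' (incident cases prevented and years with T2DM averted per intervention,
#' with percentage reductions across the arm's whole target population,
#' enrolled or not) and the annual/cumulative incremental discounted cost
#' streams with their share of the total diabetes budget.
#'
#' @param results Named list of all 12 `strategy_result`s.
#' @param pop A [population_config()].
#' @return List of data frames `outcomes` and `cost_streams`.
#' @export
report_population <- function(results, pop) {
  stopifnot(inherits(pop, "population_config"))
  active <- setdiff(STRATEGIES, "NONE")
  outcomes <- do.call(rbind, lapply(COHORTS, function(co) {
    ref <- result_of(results, co, "NONE")
    n_enrolled <- cascade_size(co, pop)
    n_arm <- pop$population_5059 * arm_prevalence(co, pop)
    do.call(rbind, lapply(active, function(st) {
      r <- result_of(results, co, st)
      cp <- cases_prevented(r, ref, n_enrolled)
      dy <- ref$mean_years_t2dm - r$mean_years_t2dm
      # population-wide percentages: non-enrolled members of the arm's
      # target population experience no-intervention outcomes
      h <- length(ref$cum_incidence)
      pct_cases <- if (ref$cum_incidence[h] > 0) {
        100 * cp$cases / (n_arm * ref$cum_incidence[h])
      } else 0
      pct_years <- if (ref$mean_years_t2dm > 0) {
        100 * n_enrolled * dy / (n_arm * ref$mean_years_t2dm)
      } else 0
      data.frame(cohort = co, strategy = st,
                 cases_prevented = cp$cases,
                 pct_reduction_cases = pct_cases,
                 years_t2dm_averted_per_person = n_enrolled * dy / n_arm,
                 pct_reduction_years = pct_years)
    }))
  }))
  cost_streams <- do.call(rbind, lapply(COHORTS, function(co) {
    ref <- result_of(results, co, "NONE")
    n_enrolled <- cascade_size(co, pop)
    do.call(rbind, lapply(active, function(st) {
      r <- result_of(results, co, st)
      bs <- budget_stream(r$cost_stream - ref$cost_stream, n_enrolled, pop)
      cbind(data.frame(cohort = co, strategy = st), bs)
    }))
  }))
  rownames(outcomes) <- rownames(cost_streams) <- NULL
  list(outcomes = outcomes, cost_streams = cost_streams)
}

#' Write report tables to CSV
#'
#' @param tables Named list of data frames (e.g. from
#'   [report_individual()] or [report_population()]).
#' @param dir Output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_reports <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to tie an output file to the run that made
#' it: an MD5 hash of the serialised parameter registry, the RNG seed, the
#' package version, a timestamp and the list of imputed placeholder
#' parameters in force.
#'
#' @param model A [t2dm_model()].
#' @param seed RNG seed used for the run (`NA` for deterministic runs).
#' @param path Optional path to also write the manifest as JSON.
#' @return The manifest list, invisibly if `path` is given.
#' @export
run_manifest <- function(model, seed = NA_integer_, path = NULL) {
  stopifnot(inherits(model, "t2dm_model"))
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(model$params, tmp, version = 2)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = seed,
    version = as.character(utils::packageVersion("prevt2dm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    imputed_parameters = imputed_names(model$params)
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
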
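#' Probabilistic sensitivity analysis
#'
#' Samples every non-fixed parameter from its moment-matched distribution
#' and re-runs all 12 cohort-by-strategy arms under each sampled parameter
#' set (common random parameters: within an iteration every arm sees the
#' same draw). The whole run is reproducible bit-for-bit from the seed. If
#' a sampled parameter set is infeasible (competing transition
#' probabilities exceeding 1 after capping), the iteration's parameters are
#' resampled and the resample count reported.
#'
#' @param model A [t2dm_model()].
#' @param n Number of iterations, >= 1.
#' @param seed Integer RNG seed.
#' @return An object of class `psa_draws`: list with `seed`, `n`,
#'   `params` (n x parameter matrix of sampled values), `results` (data
#'   frame with `iter`, `cohort`, `strategy`, `cost`, `qalys`,
#'   `incidence_final`) and `resamples`.
#' @export
run_psa <- function(model, n, seed) {
  stopifnot(inherits(model, "t2dm_model"), n >= 1)
  set.seed(seed)
  specs <- model$params
  sampled <- names(specs)[vapply(specs, function(s) {
    s$family != "fixed" && s$se > 0
  }, logical(1))]
  sampled <- sort(sampled)
  draws <- matrix(rep(param_means(specs), each = n), nrow = n,
                  dimnames = list(NULL, names(specs)))
  for (nm in sampled) {
    draws[, nm] <- draw_param(specs[[nm]], n)
  }
  resamples <- 0L
  rows <- vector("list", n)
  for (it in seq_len(n)) {
    tries <- 0L
    repeat {
      res <- tryCatch(run_strategies(model, values = draws[it, ]),
                      error = function(e) e)
      if (!inherits(res, "error")) break
      tries <- tries + 1L
      if (tries > 100L) {
        stop(sprintf("PSA iteration %d failed after 100 resamples: %s",
                     it, conditionMessage(res)), call. = FALSE)
      }
      message(sprintf("PSA iteration %d: infeasible draw resampled (%s)",
                      it, conditionMessage(res)))
      for (nm in sampled) {
        draws[it, nm] <- draw_param(specs[[nm]], 1)
      }
      resamples <- resamples + 1L
    }
    tab <- results_table(res)
    tab$iter <- it
    rows[[it]] <- tab[c("iter", "cohort", "strategy", "cost", "qalys",
                        "incidence_final")]
  }
  structure(
    list(seed = seed, n = n, params = draws,
         results = do.call(rbind, rows), resamples = resamples),
    class = "psa_draws"
  )
}

#' PSA draws for one cohort in [ceac()] format
#'
#' @param psa A [run_psa()] object.
#' @param cohort One of `"IGT"`, `"IFG"`, `"HBA1C"`.
#' @return Data frame with columns `iter`, `strategy`, `cost`, `qalys`.
#' @export
psa_cohort_draws <- function(psa, cohort) {
  stopifnot(inherits(psa, "psa_draws"))
  cohort <- match.arg(cohort, COHORTS)
  d <- psa$results[psa$results$cohort == cohort,
                   c("iter", "strategy", "cost", "qalys")]
  rownames(d) <- NULL
  d
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the deterministic model with each parameter in turn multiplied
#' by `1 - swing` and `1 + swing` and records the headline
#' cost-effectiveness ratio of `strategy` versus no intervention in
#' `cohort`. Output is sorted by the width of the ICER range (a tornado
#' table).
#'
#' @param model A [t2dm_model()].
#' @param params Parameter names to vary; defaults to the full registry.
#' @param cohort,strategy Arm whose CER versus `"NONE"` is tracked.
#' @param swing Proportional perturbation (default 0.10).
#' @return Data frame with columns `param`, `icer_low` (value at
#'   `1 - swing`), `icer_high` (at `1 + swing`), `range`, sorted by
#'   decreasing `range`.
#' @export
tornado_one_way <- function(model, params = NULL, cohort = "IGT",
                            strategy = "PRAGMATIC", swing = 0.10) {
  stopifnot(inherits(model, "t2dm_model"))
  cohort <- match.arg(cohort, COHORTS)
  strategy <- match.arg(strategy, setdiff(STRATEGIES, "NONE"))
  if (is.null(params)) params <- names(model$params)
  unknown <- setdiff(params, names(model$params))
  if (length(unknown)) {
    stop(sprintf("unknown parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  headline <- function(m) {
    res <- run_arm(assemble_arm(m, cohort, strategy))
    ref <- run_arm(assemble_arm(m, cohort, "NONE"))
    cer_vs_reference(res, ref)$cer
  }
  rows <- lapply(params, function(pn) {
    lo <- headline(perturb(model, pn, 1 - swing))
    hi <- headline(perturb(model, pn, 1 + swing))
    data.frame(param = pn, icer_low = lo, icer_high = hi,
               range = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  out
}

#' Named scenario analyses
#'
#' Applies one of the documented deterministic scenarios to a model and
#' re-runs all arms:
#' \describe{
#'   \item{`extended_effect`}{Pragmatic-lifestyle and metformin relative
#'     risks persist to `extended_until` (default the full horizon) instead
#'     of their base-case windows.}
#'   \item{`who_ifg`}{Replaces the IFG parameter block with a supplied set
#'     of WHO-criteria values (`ifg_block`, a named list of
#'     [param_spec()]s or numeric means); required, as no such values are
#'     bundled.}
#'   \item{`cost_up_20` / `cost_down_20`}{All intervention cost parameters
#'     multiplied by 1.2 / 0.8.}
#'   \item{`unrelated_costs`}{Adds an annual unrelated healthcare cost to
#'     every alive state (default GBP 2,000/year).}
#' }
#' The input model is never modified.
#'
#' @param model A [t2dm_model()].
#' @param name Scenario name.
#' @param ifg_block Parameter overrides for `who_ifg`.
#' @param unrelated_annual_cost Annual cost for `unrelated_costs`.
#' @param extended_until Final model year of intervention effect for
#'   `extended_effect`; defaults to the horizon.
#' @return List with `name`, `model` (the modified copy) and `results`
#'   (all 12 arms re-run).
#' @export
run_scenario <- function(model,
                         name = c("extended_effect", "who_ifg",
                                  "cost_up_20", "cost_down_20",
                                  "unrelated_costs"),
                         ifg_block = NULL, unrelated_annual_cost = 2000,
                         extended_until = NULL) {
  stopifnot(inherits(model, "t2dm_model"))
  name <- match.arg(name)
  m <- model
  if (name == "extended_effect") {
    until <- if (is.null(extended_until)) m$globals$horizon_years
             else extended_until
    m$schedule$PRAGMATIC$during_end <- until
    m$schedule$PRAGMATIC$cease <- until
    m$schedule$METFORMIN$cease_by_cohort[] <- until
  } else if (name == "who_ifg") {
    if (is.null(ifg_block) || !length(ifg_block)) {
      stop(paste("scenario 'who_ifg' requires an 'ifg_block' of WHO-criteria",
                 "parameter values; none are bundled"), call. = FALSE)
    }
    unknown <- setdiff(names(ifg_block), names(m$params))
    if (length(unknown)) {
      stop(sprintf("ifg_block references unknown parameter(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    for (nm in names(ifg_block)) {
      ov <- ifg_block[[nm]]
      if (inherits(ov, "param_spec")) {
        m$params[[nm]] <- ov
      } else {
        old <- m$params[[nm]]
        m$params[[nm]] <- param_spec(old$name, as.numeric(ov), old$se,
                                     old$family, "imputed")
      }
    }
  } else if (name %in% c("cost_up_20", "cost_down_20")) {
    f <- if (name == "cost_up_20") 1.2 else 0.8
    for (nm in c("cost_prag_y1", "cost_prag_y2", "cost_int_y1",
                 "cost_int_y2", "cost_int_y3", "cost_met_annual")) {
      m <- perturb(m, nm, f)
    }
  } else if (name == "unrelated_costs") {
    if (unrelated_annual_cost < 0) {
      stop("'unrelated_annual_cost' must be >= 0", call. = FALSE)
    }
    m$globals$unrelated_annual_cost <- unrelated_annual_cost
  }
  list(name = name, model = m, results = run_strategies(m))
}
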
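N_TUNNEL <- 15L

#' Names of the expanded state space
#'
#' Four clinical states, with T2DM expanded into 15 tunnel states indexed
#' by years since onset so that the duration-dependent T2DM cost ramp can
#' be represented in a Markov chain; the 15th tunnel state is
#' self-absorbing until death. Death is absorbing; normoglycaemia cannot
#' transition to T2DM within one cycle.
#'
#' @return Character vector of 18 state names.
#' @export
state_names <- function() {
  c("NGT", "IH", paste0("T2DM_y", seq_len(N_TUNNEL)), "DEAD")
}

#' Intervention relative risk of progression in a given model year
#'
#' Returns the relative risk applied to the annual intermediate-
#' hyperglycaemia to T2DM transition in model year `t` (years are 1-based;
#' everyone enters intermediate hyperglycaemia at t = 0). The pragmatic
#' programme's effect covers its 2 delivery years only; the intensive
#' programme applies its in-programme effect in years 1-3 and an attenuated
#' post-programme effect through year 10; metformin applies a constant
#' effect through year 15 (IGT/IFG) or year 10 (HbA1c); outside these
#' windows, and with no intervention, the relative risk is 1.
#'
#' @param intervention Intervention profile list from a `t2dm_arm`
#'   (`NULL` for no intervention).
#' @param t Model year, integer >= 1 (vectorised).
#' @return Numeric vector of relative risks.
#' @export
rr_at <- function(intervention, t) {
  if (any(t < 1)) {
    stop("model year t must be >= 1", call. = FALSE)
  }
  if (is.null(intervention)) {
    return(rep(1, length(t)))
  }
  ifelse(t <= intervention$rr_during_end, intervention$rr_during,
         ifelse(t <= intervention$rr_cease_year, intervention$rr_post, 1))
}

#' Convert an annual probability under a hazard ratio
#'
#' Applies a hazard ratio on the (constant-within-cycle) hazard scale:
#' `p' = 1 - (1 - p)^hr`, exact for annual cycles.
#'
#' @param p Annual probability in `[0, 1]` (vectorised).
#' @param hr Hazard ratio, > 0.
#' @return Adjusted probability.
#' @export
adjust_probability_for_hazard <- function(p, hr) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("probability must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(hr) | hr <= 0)) {
    stop("hazard ratio must be > 0", call. = FALSE)
  }
  1 - (1 - p)^hr
}

#' Annual cost of T2DM by years since onset
#'
#' Costs of T2DM rise linearly from the year-1 ramp start to the year-15
#' ramp end (reflecting accumulating complications) and plateau thereafter.
#'
#' @param years_since_onset Integer >= 1 (vectorised).
#' @param payoffs Payoff list from a `t2dm_arm` (fields `cost_t2dm_y1`,
#'   `cost_t2dm_y15`).
#' @return Annual cost, GBP.
#' @export
t2dm_annual_cost <- function(years_since_onset, payoffs) {
  if (any(years_since_onset < 1)) {
    stop("years_since_onset must be >= 1", call. = FALSE)
  }
  k <- pmin(years_since_onset, N_TUNNEL)
  payoffs$cost_t2dm_y1 +
    (k - 1) / (N_TUNNEL - 1) * (payoffs$cost_t2dm_y15 - payoffs$cost_t2dm_y1)
}

# per-cycle transition ingredients shared by the matrix builder and the
# trace engine; death is applied first, disease transitions split the
# survivors (competing-risk decomposition)
cycle_rates <- function(arm, t) {
  g <- arm$globals
  age <- g$start_age + t - 1
  idx <- match(age, arm$life_table$age)
  if (is.na(idx)) {
    stop(sprintf("life table does not cover age %g", age), call. = FALSE)
  }
  qb <- arm$life_table$qx[idx]
  tr <- arm$transitions
  p12 <- min(1, tr$p_ih_to_t2dm * rr_at(arm$intervention, t))
  p10 <- tr$p_ih_to_ngt
  if (p12 + p10 > 1) {
    stop(sprintf(
      "state 'IH': competing transition probabilities exceed 1 (%.4f + %.4f)",
      p12, p10), call. = FALSE)
  }
  list(
    d_ngt = qb,
    d_ih = adjust_probability_for_hazard(qb, tr$hr_death_ih),
    d_t2dm = adjust_probability_for_hazard(qb, tr$hr_death_t2dm),
    p_ih_t2dm = p12, p_ih_ngt = p10, p_ngt_ih = tr$p_ngt_to_ih
  )
}

#' Annual transition matrix for one model year
#'
#' Builds the row-stochastic transition matrix over the expanded state
#' space for model year `t`. Background mortality is read from the life
#' table at the cohort's age in year `t` and hazard-adjusted for
#' intermediate hyperglycaemia and T2DM; the surviving mass is then split
#' among disease transitions, with the progression probability multiplied
#' by the intervention's relative risk for that year (capped at 1).
#' Normoglycaemia cannot reach T2DM in one cycle, T2DM tunnel states only
#' advance (or die), and death is absorbing.
#'
#' @param arm A `t2dm_arm` from [assemble_arm()].
#' @param t Model year, 1-based.
#' @return An 18 x 18 row-stochastic matrix with dimnames
#'   [state_names()].
#' @export
build_transition_matrix <- function(arm, t) {
  stopifnot(inherits(arm, "t2dm_arm"), length(t) == 1L, t >= 1)
  r <- cycle_rates(arm, t)
  s <- state_names()
  n <- length(s)
  M <- matrix(0, n, n, dimnames = list(s, s))
  M["NGT", "DEAD"] <- r$d_ngt
  M["NGT", "IH"] <- (1 - r$d_ngt) * r$p_ngt_ih
  M["NGT", "NGT"] <- (1 - r$d_ngt) * (1 - r$p_ngt_ih)
  M["IH", "DEAD"] <- r$d_ih
  M["IH", "T2DM_y1"] <- (1 - r$d_ih) * r$p_ih_t2dm
  M["IH", "NGT"] <- (1 - r$d_ih) * r$p_ih_ngt
  M["IH", "IH"] <- (1 - r$d_ih) * (1 - r$p_ih_t2dm - r$p_ih_ngt)
  for (k in seq_len(N_TUNNEL)) {
    from <- paste0("T2DM_y", k)
    to <- paste0("T2DM_y", min(k + 1, N_TUNNEL))
    M[from, "DEAD"] <- r$d_t2dm
    M[from, to] <- M[from, to] + (1 - r$d_t2dm)
  }
  M["DEAD", "DEAD"] <- 1
  M
}

#' Run the cohort simulation
#'
#' Propagates the state-occupancy distribution over the model horizon with
#' annual cycles. The cohort enters entirely in intermediate
#' hyperglycaemia at cycle 0 (override with `init` for experiments); each
#' cycle applies the year-specific transition dynamics of
#' [build_transition_matrix()]. Probability mass is conserved every cycle.
#'
#' @param arm A `t2dm_arm`.
#' @param init Optional length-18 initial occupancy vector summing to 1.
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   ((horizon + 1) x 18 matrix, rows = cycles 0..horizon), `new_t2dm`
#'   (per-cycle probability mass entering the first T2DM tunnel state) and
#'   the arm's cohort/strategy labels.
#' @export
run_cohort <- function(arm, init = NULL) {
  stopifnot(inherits(arm, "t2dm_arm"))
  h <- arm$globals$horizon_years
  s <- state_names()
  n <- length(s)
  if (is.null(init)) {
    init <- stats::setNames(numeric(n), s)
    init["IH"] <- 1
  } else {
    stopifnot(length(init) == n, abs(sum(init) - 1) < 1e-10, all(init >= 0))
    init <- stats::setNames(as.numeric(init), s)
  }
  occ <- matrix(0, h + 1, n, dimnames = list(0:h, s))
  occ[1, ] <- init
  new_t2dm <- numeric(h + 1)  # index t+1 holds inflow during cycle t
  i_t2 <- 2L + seq_len(N_TUNNEL)  # T2DM tunnel columns
  v <- init
  for (t in seq_len(h)) {
    r <- cycle_rates(arm, t)
    ngt_s <- v[["NGT"]] * (1 - r$d_ngt)
    ih_s <- v[["IH"]] * (1 - r$d_ih)
    t2_s <- v[i_t2] * (1 - r$d_t2dm)
    dead <- v[["DEAD"]] + v[["NGT"]] * r$d_ngt + v[["IH"]] * r$d_ih +
      sum(v[i_t2]) * r$d_t2dm
    inflow <- ih_s * r$p_ih_t2dm
    v_new <- v
    v_new[["NGT"]] <- ngt_s * (1 - r$p_ngt_ih) + ih_s * r$p_ih_ngt
    v_new[["IH"]] <- ih_s * (1 - r$p_ih_t2dm - r$p_ih_ngt) +
      ngt_s * r$p_ngt_ih
    v_new[i_t2] <- c(inflow, t2_s[seq_len(N_TUNNEL - 1)])
    v_new[i_t2[N_TUNNEL]] <- v_new[i_t2[N_TUNNEL]] + t2_s[N_TUNNEL]
    v_new[["DEAD"]] <- dead
    v <- v_new
    occ[t + 1, ] <- v
    new_t2dm[t + 1] <- inflow
  }
  structure(
    list(occupancy = occ, new_t2dm = new_t2dm,
         cohort = arm$cohort, strategy = arm$strategy),
    class = "cohort_trace"
  )
}

#' Cumulative T2DM incidence by cycle
#'
#' Probability that a cohort member has developed T2DM by cycle `t`: the
#' running sum of per-cycle inflow into the first T2DM tunnel state.
#'
#' @param trace A [run_cohort()] trace.
#' @param t Cycle, `0 <= t <= horizon` (vectorised).
#' @return Cumulative incidence, non-decreasing in `t`.
#' @export
cumulative_incidence <- function(trace, t) {
  stopifnot(inherits(trace, "cohort_trace"))
  h <- length(trace$new_t2dm) - 1L
  if (any(t < 0 | t > h)) {
    stop(sprintf("cycle t must lie in [0, %d]", h), call. = FALSE)
  }
  cumsum(trace$new_t2dm)[t + 1]
}

#' Expected years lived with T2DM
#'
#' Undiscounted expected number of years spent in any T2DM tunnel state
#' over the model horizon (cycle-start convention: cycles 0 to
#' horizon - 1).
#'
#' @param trace A [run_cohort()] trace.
#' @return Expected years, in `[0, horizon]`.
#' @export
mean_years_t2dm <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  h <- nrow(trace$occupancy) - 1L
  i_t2 <- 2L + seq_len(N_TUNNEL)
  sum(trace$occupancy[seq_len(h), i_t2])
}

#' Discounted costs and QALYs for one arm
#'
#' Accumulates per-cycle rewards over the trace: state costs (with the
#' duration-dependent T2DM ramp), intervention costs and incremental
#' utility accruing to the intermediate-hyperglycaemia occupancy during the
#' programme (metformin accrues for as long as the participant remains in
#' intermediate hyperglycaemia), optional unrelated healthcare costs on all
#' alive states, and state utilities. Rewards use the cycle-start
#' convention (cycles 0 to horizon - 1) discounted by
#' `(1 + discount_rate)^-t`; a half-cycle (trapezoidal) correction is
#' applied instead when `globals$half_cycle` is `TRUE`.
#'
#' @param trace A [run_cohort()] trace produced from `arm`.
#' @param arm The `t2dm_arm` that produced `trace`.
#' @return An object of class `strategy_result`: discounted and
#'   undiscounted cost and QALY totals, discounted per-cycle cost and QALY
#'   streams, cost components (states / intervention / unrelated),
#'   cumulative-incidence curve, 10- and 50-year incidence, and expected
#'   years lived with T2DM.
#' @export
accumulate <- function(trace, arm) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(arm, "t2dm_arm"))
  if (!identical(trace$cohort, arm$cohort) ||
      !identical(trace$strategy, arm$strategy)) {
    stop("trace and arm configuration do not match", call. = FALSE)
  }
  g <- arm$globals
  h <- g$horizon_years
  p <- arm$payoffs
  occ <- trace$occupancy
  if (g$half_cycle) {
    occ_eff <- (occ[seq_len(h), , drop = FALSE] +
                occ[seq_len(h) + 1L, , drop = FALSE]) / 2
  } else {
    occ_eff <- occ[seq_len(h), , drop = FALSE]
  }
  state_cost <- c(p$cost_ngt, p$cost_ih,
                  t2dm_annual_cost(seq_len(N_TUNNEL), p), 0)
  state_util <- c(p$util_ngt, p$util_ih, rep(p$util_t2dm, N_TUNNEL), 0)
  alive <- 1 - occ_eff[, "DEAD"]
  cost_states <- as.numeric(occ_eff %*% state_cost)
  cost_unrelated <- g$unrelated_annual_cost * alive
  qaly_states <- as.numeric(occ_eff %*% state_util)

  iv <- arm$intervention
  cost_iv <- numeric(h)
  qaly_iv <- numeric(h)
  if (!is.null(iv)) {
    base_occ <- if (g$accrue_to_all) alive else occ_eff[, "IH"]
    years <- seq_len(h)
    if (is.finite(iv$duration_years)) {
      on <- years <= iv$duration_years
      cost_iv[on] <- iv$annual_costs[years[on]] * base_occ[on]
      qaly_iv[on] <- iv$incremental_utility * base_occ[on]
    } else {
      # open-ended therapy: cost and utility while in IH, every year
      cost_iv <- iv$annual_costs[1] * base_occ
      qaly_iv <- iv$incremental_utility * base_occ
    }
  }
  disc <- (1 + g$discount_rate)^-(0:(h - 1))
  cost_stream <- (cost_states + cost_unrelated + cost_iv) * disc
  qaly_stream <- (qaly_states + qaly_iv) * disc
  cum_inc <- cumulative_incidence(trace, 0:h)
  structure(
    list(cohort = arm$cohort, strategy = arm$strategy,
         cost = sum(cost_stream), qalys = sum(qaly_stream),
         cost_undiscounted = sum(cost_states + cost_unrelated + cost_iv),
         qalys_undiscounted = sum(qaly_states + qaly_iv),
         cost_components = list(
           states = sum(cost_states * disc),
           intervention = sum(cost_iv * disc),
           unrelated = sum(cost_unrelated * disc)),
         cost_stream = cost_stream, qaly_stream = qaly_stream,
         cum_incidence = cum_inc,
         incidence_10y = cum_inc[min(11, h + 1)],
         incidence_final = cum_inc[h + 1],
         mean_years_t2dm = mean_years_t2dm(trace)),
    class = "strategy_result"
  )
}

#' Run one arm end-to-end
#'
#' @param arm A `t2dm_arm`.
#' @return An [accumulate()] result.
#' @export
run_arm <- function(arm) {
  accumulate(run_cohort(arm), arm)
}

#' Run all 12 cohort-by-strategy arms of a model
#'
#' @inheritParams build_arms
#' @return Named list of `strategy_result`s (names like
#'   `"IGT.PRAGMATIC"`).
#' @export
run_strategies <- function(model, values = NULL) {
  lapply(build_arms(model, values), run_arm)
}

#' Tidy summary of a result set
#'
#' @param results A list of `strategy_result`s.
#' @return Data frame with one row per arm.
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(unname(results), function(r) {
    data.frame(cohort = r$cohort, strategy = r$strategy,
               cost = r$cost, qalys = r$qalys,
               incidence_10y = r$incidence_10y,
               incidence_final = r$incidence_final,
               mean_years_t2dm = r$mean_years_t2dm)
  }))
}

#' Export a cohort trace as a data frame
#'
#' One row per cycle, one column per state, plus the per-cycle new-T2DM
#' inflow; suitable for writing to CSV.
#'
#' @param trace A [run_cohort()] trace.
#' @return Data frame.
#' @export
trace_table <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  cbind(data.frame(cycle = 0:(nrow(trace$occupancy) - 1L)),
        as.data.frame(trace$occupancy, row.names = FALSE),
        data.frame(new_t2dm = trace$new_t2dm))
}
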
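test_that("relative-risk schedules reproduce every printed cell", {
  m <- replication_config()
  rr <- function(cohort, strategy, t) {
    rr_at(assemble_arm(m, cohort, strategy)$intervention, t)
  }
  # pragmatic: effect only during the 2 delivery years
  for (co in c("IGT", "IFG", "HBA1C")) {
    expect_equal(rr(co, "PRAGMATIC", 1:2), c(0.74, 0.74))
    expect_equal(rr(co, "PRAGMATIC", 3), 1)
  }
  # intensive: in-programme years 1-3, attenuated to year 10, then none
  expect_equal(rr("IFG", "INTENSIVE", 1:3), rep(0.63, 3))
  expect_equal(rr("IGT", "INTENSIVE", 1:3), rep(0.55, 3))
  expect_equal(rr("HBA1C", "INTENSIVE", 1:3), rep(0.71, 3))
  expect_equal(rr("IFG", "INTENSIVE", 4:10), rep(0.80, 7))
  expect_equal(rr("IGT", "INTENSIVE", 4:10), rep(0.80, 7))
  expect_equal(rr("HBA1C", "INTENSIVE", 4:10), rep(0.71, 7))
  expect_equal(rr("IGT", "INTENSIVE", 11), 1)
  # metformin: constant through year 15 (IGT/IFG) or 10 (HbA1c)
  expect_equal(rr("IGT", "METFORMIN", c(1, 15)), c(0.82, 0.82))
  expect_equal(rr("IFG", "METFORMIN", c(1, 15)), c(0.82, 0.82))
  expect_equal(rr("IGT", "METFORMIN", 16), 1)
  expect_equal(rr("HBA1C", "METFORMIN", c(1, 10)), c(0.62, 0.62))
  expect_equal(rr("HBA1C", "METFORMIN", 11), 1)
  # no intervention: always 1
  expect_equal(rr_at(NULL, 1:50), rep(1, 50))
  expect_error(rr_at(NULL, 0), ">= 1")
})

test_that("hazard-ratio probability conversion is exact on the hazard scale", {
  expect_equal(adjust_probability_for_hazard(0.1, 1), 0.1)
  expect_equal(adjust_probability_for_hazard(0, 5), 0)
  expect_equal(adjust_probability_for_hazard(0.1, 2), 0.19)
  # cross-check against the rate-scale conversion 1 - exp(-hr * rate)
  p <- 0.07
  hr <- 1.8
  expect_equal(adjust_probability_for_hazard(p, hr),
               1 - exp(-hr * (-log(1 - p))), tolerance = 1e-14)
  expect_error(adjust_probability_for_hazard(1.2, 1), "\\[0, 1\\]")
  expect_error(adjust_probability_for_hazard(0.1, 0), "> 0")
})

test_that("T2DM annual cost ramps linearly over 15 years then plateaus", {
  p <- list(cost_t2dm_y1 = 1179, cost_t2dm_y15 = 2939)
  expect_equal(t2dm_annual_cost(1, p), 1179)
  expect_equal(t2dm_annual_cost(8, p), 2059)   # linear midpoint
  expect_equal(t2dm_annual_cost(15, p), 2939)
  expect_equal(t2dm_annual_cost(20, p), 2939)  # plateau
  diffs <- diff(t2dm_annual_cost(1:15, p))
  expect_equal(diffs, rep((2939 - 1179) / 14, 14))
  expect_error(t2dm_annual_cost(0, p), ">= 1")
})

test_that("transition matrices are row-stochastic with the required zeros", {
  m <- replication_config()
  for (key in c("IGT.NONE", "IFG.INTENSIVE", "HBA1C.METFORMIN")) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    arm <- assemble_arm(m, parts[1], parts[2])
    for (t in c(1, 5, 25, 50)) {
      M <- build_transition_matrix(arm, t)
      expect_equal(unname(rowSums(M)), rep(1, 18), tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(M["NGT", "T2DM_y1"], 0)           # no direct NGT -> T2DM
      expect_equal(M["DEAD", "DEAD"], 1)             # death absorbing
      expect_equal(M["T2DM_y3", "IH"], 0)            # no recovery from T2DM
      expect_equal(M["T2DM_y3", "NGT"], 0)
      expect_equal(sum(M["T2DM_y15", c("T2DM_y15", "DEAD")]), 1)
    }
  }
  # with mortality and reversion off, IH -> first tunnel equals the printed
  # IGT annual incidence
  arm <- toy_arm(transitions = list(p_ih_to_t2dm = 0.0454))
  expect_equal(build_transition_matrix(arm, 1)["IH", "T2DM_y1"], 0.0454)
})

test_that("cohort traces conserve mass and match closed forms", {
  # frozen dynamics: cohort remains entirely in IH
  tr <- run_cohort(make_toy_fixture("frozen"))
  expect_equal(unname(tr$occupancy[, "IH"]), rep(1, 51))
  expect_equal(unname(rowSums(tr$occupancy)), rep(1, 51), tolerance = 1e-10)

  # geometric decay: survival halves every cycle
  tr <- run_cohort(make_toy_fixture("geometric"))
  alive <- 1 - tr$occupancy[, "DEAD"]
  expect_equal(unname(alive), 0.5^(0:50), tolerance = 1e-12)

  # full model: conservation and monotone death at every cycle
  m <- replication_config()
  tr <- run_cohort(assemble_arm(m, "IGT", "INTENSIVE"))
  expect_equal(unname(rowSums(tr$occupancy)), rep(1, 51), tolerance = 1e-10)
  expect_true(all(diff(tr$occupancy[, "DEAD"]) >= 0))
  expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 1))
})

test_that("iterative propagation matches the matrix-product oracle", {
  m <- replication_config()
  arms <- list(make_toy_fixture("homogeneous"),
               assemble_arm(m, "IGT", "INTENSIVE"),
               assemble_arm(m, "HBA1C", "METFORMIN"))
  for (arm in arms) {
    tr <- run_cohort(arm)
    expect_equal(tr$occupancy, matrix_trace(arm), tolerance = 1e-10)
  }
  # for the time-homogeneous fixture the t-th matrix power reproduces the
  # occupancy at cycle t
  arm <- make_toy_fixture("homogeneous")
  M <- build_transition_matrix(arm, 1)
  tr <- run_cohort(arm)
  v <- tr$occupancy[1, ]
  P <- diag(18)
  for (t in 1:50) {
    P <- P %*% M
    expect_equal(unname(tr$occupancy[t + 1, ]), unname(as.numeric(v %*% P)),
                 tolerance = 1e-10)
  }
})

test_that("cumulative incidence follows its closed form and is monotone", {
  tr <- run_cohort(make_toy_fixture("frozen"))
  expect_equal(cumulative_incidence(tr, 0), 0)
  expect_equal(cumulative_incidence(tr, 0:50), rep(0, 51))

  # constant hazard 0.1, no death or reversion: 1 - 0.9^t
  arm <- toy_arm(transitions = list(p_ih_to_t2dm = 0.1))
  tr <- run_cohort(arm)
  expect_equal(cumulative_incidence(tr, 0:50), 1 - 0.9^(0:50),
               tolerance = 1e-12)
  expect_true(all(diff(cumulative_incidence(tr, 0:50)) >= 0))
  expect_error(cumulative_incidence(tr, 51), "\\[0, 50\\]")
})

test_that("years lived with T2DM sum the tunnel occupancy", {
  expect_equal(mean_years_t2dm(run_cohort(make_toy_fixture("frozen"))), 0)

  # whole cohort in T2DM, immortal: upper bound of one year per cycle
  arm <- toy_arm()
  init <- stats::setNames(numeric(18), state_names())
  init["T2DM_y1"] <- 1
  tr <- run_cohort(arm, init = init)
  expect_equal(mean_years_t2dm(tr), 50)

  # brute-force sum over the occupancy table
  tr <- run_cohort(make_toy_fixture("homogeneous"))
  tun <- paste0("T2DM_y", 1:15)
  expect_equal(mean_years_t2dm(tr), sum(tr$occupancy[1:50, tun]))
})

test_that("reward accumulation follows the cycle-start discounting convention", {
  # unit utility, zero cost, immortal, 2 cycles at 3.5%
  arm <- toy_arm(horizon = 2,
                 payoffs = list(cost_ngt = 0, cost_ih = 0, cost_t2dm_y1 = 0,
                                cost_t2dm_y15 = 0, util_ih = 1))
  res <- run_arm(arm)
  expect_equal(res$qalys, 1 + 1 / 1.035, tolerance = 1e-10)
  expect_equal(res$cost, 0)

  # zero discounting, frozen IGT cohort: 50 years at the IH cost of care
  arm <- toy_arm(discount = 0)
  res <- run_arm(arm)
  expect_equal(res$cost, 50 * 946)
  expect_equal(res$cost, res$cost_undiscounted)
  expect_equal(res$qalys, res$qalys_undiscounted)

  # metformin cost accrues only to intermediate hyperglycaemia: a cohort
  # starting entirely in T2DM accrues no intervention cost
  m <- replication_config()
  arm <- assemble_arm(m, "IGT", "METFORMIN")
  init <- stats::setNames(numeric(18), state_names())
  init["T2DM_y1"] <- 1
  res <- accumulate(run_cohort(arm, init = init), arm)
  expect_equal(res$cost_components$intervention, 0)

  # mismatched trace and arm are rejected
  tr <- run_cohort(assemble_arm(m, "IGT", "NONE"))
  expect_error(accumulate(tr, assemble_arm(m, "IFG", "NONE")),
               "do not match")
})

test_that("discounting and dynamics respond monotonically to inputs", {
  m <- replication_config()
  base_arm <- assemble_arm(m, "IGT", "PRAGMATIC")
  base <- run_arm(base_arm)

  # weakening the intervention (RR toward 1) raises incidence, lowers QALYs
  prev_inc <- -Inf
  prev_q <- Inf
  for (rr in c(0.74, 0.85, 0.95, 1)) {
    arm <- base_arm
    arm$intervention$rr_during <- rr
    res <- run_arm(arm)
    expect_gte(res$incidence_final, prev_inc)
    expect_lte(res$qalys, prev_q)
    prev_inc <- res$incidence_final
    prev_q <- res$qalys
  }

  # raising the discount rate never raises discounted totals
  prev <- c(Inf, Inf)
  for (r in c(0, 0.035, 0.06)) {
    arm <- base_arm
    arm$globals$discount_rate <- r
    res <- run_arm(arm)
    expect_lte(res$cost, prev[1])
    expect_lte(res$qalys, prev[2])
    prev <- c(res$cost, res$qalys)
  }
})

test_that("trace export carries one row per cycle and the inflow column", {
  tr <- run_cohort(make_toy_fixture("homogeneous"))
  tab <- trace_table(tr)
  expect_equal(nrow(tab), 51)
  expect_true(all(c("cycle", "NGT", "IH", "T2DM_y1", "DEAD", "new_t2dm")
                  %in% names(tab)))
  expect_equal(tab$new_t2dm, tr$new_t2dm)
})
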
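small_model <- function(horizon = 15) {
  replication_config(globals = global_params(horizon_years = horizon))
}

test_that("PSA is bit-reproducible under a fixed seed", {
  m <- small_model()
  p1 <- run_psa(m, 3, seed = 99)
  p2 <- run_psa(m, 3, seed = 99)
  expect_identical(p1$params, p2$params)
  expect_identical(p1$results, p2$results)
  p3 <- run_psa(m, 3, seed = 100)
  expect_false(identical(p1$results$cost, p3$results$cost))
})

test_that("an all-fixed registry degenerates to the deterministic run", {
  m <- small_model()
  m$params <- lapply(m$params, function(s) {
    param_spec(s$name, s$mean, 0, "fixed", s$source)
  })
  names(m$params) <- vapply(m$params, function(s) s$name, character(1))
  psa <- run_psa(m, 2, seed = 1)
  det <- results_table(run_strategies(m))
  for (it in 1:2) {
    sub <- psa$results[psa$results$iter == it, ]
    expect_equal(sub$cost, det$cost, tolerance = 1e-12)
    expect_equal(sub$qalys, det$qalys, tolerance = 1e-12)
  }
})

test_that("PSA sample means agree with configured means", {
  m <- small_model()
  set.seed(5)
  psa <- run_psa(m, 400, seed = 5)
  sampled <- names(m$params)[vapply(m$params, function(s) s$se > 0,
                                    logical(1))]
  for (nm in sampled) {
    s <- m$params[[nm]]
    mc_se <- s$se / sqrt(psa$n)
    expect_lt(abs(mean(psa$params[, nm]) - s$mean), 4 * mc_se)
  }
  # fixed parameters never vary
  expect_equal(stats::sd(psa$params[, "cost_prag_y1"]), 0)
})

test_that("tornado analysis brackets the base case and ranks by range", {
  m <- small_model(10)
  params <- c("p_t2dm_igt", "util_incr_lifestyle", "cost_state_ngt",
              "cost_prag_y1")
  tt <- tornado_one_way(m, params = params, cohort = "IGT",
                        strategy = "PRAGMATIC")
  expect_setequal(tt$param, params)
  expect_equal(tt$range, sort(tt$range, decreasing = TRUE))

  # a parameter with no pathway into the IGT pragmatic-vs-none contrast
  # has zero range when reversion to normoglycaemia is impossible
  m0 <- m
  m0$params$p_revert_igt <- param_spec("p_revert_igt", 0, source = "imputed")
  m0$params$p_ngt_to_ih <- param_spec("p_ngt_to_ih", 0, source = "imputed")
  tt0 <- tornado_one_way(m0, params = c("util_ngt", "p_t2dm_igt"),
                         cohort = "IGT", strategy = "PRAGMATIC")
  expect_equal(tt0$range[tt0$param == "util_ngt"], 0)
  expect_gt(tt0$range[tt0$param == "p_t2dm_igt"], 0)

  # permutation of the parameter list does not change the ranking
  tt2 <- tornado_one_way(m, params = rev(params), cohort = "IGT",
                         strategy = "PRAGMATIC")
  expect_equal(tt$param, tt2$param)
  expect_error(tornado_one_way(m, params = "nope"), "unknown parameter")
})

test_that("scenarios modify a copy and never the base model", {
  m <- small_model(12)
  base_means <- param_means(m$params)
  base_results <- results_table(run_strategies(m))

  sc <- run_scenario(m, "cost_down_20")
  expect_equal(sc$model$params$cost_prag_y1$mean, 162.752, tolerance = 1e-12)
  expect_equal(sc$model$params$cost_int_y1$mean, 1225 * 0.8)
  # purity: base model untouched, base results unchanged
  expect_identical(param_means(m$params), base_means)
  expect_equal(results_table(run_strategies(m)), base_results)

  sc <- run_scenario(m, "unrelated_costs", unrelated_annual_cost = 0)
  expect_equal(results_table(sc$results), base_results)
  sc2 <- run_scenario(m, "unrelated_costs", unrelated_annual_cost = 2000)
  expect_true(all(results_table(sc2$results)$cost > base_results$cost))

  expect_error(run_scenario(m, "who_ifg"), "ifg_block")
  sc3 <- run_scenario(m, "who_ifg",
                      ifg_block = list(p_t2dm_ifg = 0.05))
  expect_equal(sc3$model$params$p_t2dm_ifg$mean, 0.05)
  expect_equal(sc3$model$params$p_t2dm_ifg$source, "imputed")
  expect_error(run_scenario(m, "who_ifg", ifg_block = list(zzz = 1)),
               "unknown parameter")
})

test_that("extending the intervention effect lowers incidence at every cycle", {
  m <- small_model(30)
  sc <- run_scenario(m, "extended_effect")
  base_tr <- run_cohort(assemble_arm(m, "IGT", "PRAGMATIC"))
  ext_tr <- run_cohort(assemble_arm(sc$model, "IGT", "PRAGMATIC"))
  h <- m$globals$horizon_years
  base_ci <- cumulative_incidence(base_tr, 0:h)
  ext_ci <- cumulative_incidence(ext_tr, 0:h)
  expect_true(all(ext_ci <= base_ci + 1e-14))
  expect_lt(ext_ci[h + 1], base_ci[h + 1])
  # metformin effect window also extends
  arm <- assemble_arm(sc$model, "IGT", "METFORMIN")
  expect_equal(rr_at(arm$intervention, h), 0.82)
})
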
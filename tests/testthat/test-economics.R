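res_like <- function(cost, qalys) list(cost = cost, qalys = qalys)

test_that("cost-effectiveness ratios handle signs and degenerate cases", {
  out <- cer_vs_reference(res_like(100, 0.01), res_like(0, 0))
  expect_equal(out$cer, 10000)
  expect_equal(out$annotation, "")

  out <- cer_vs_reference(res_like(0, 0), res_like(0, 0))
  expect_true(is.na(out$cer))
  expect_match(out$annotation, "undefined")

  out <- cer_vs_reference(res_like(-5, 0.1), res_like(0, 0))
  expect_equal(out$cer, -50)
  expect_equal(out$annotation, "dominant")

  out <- cer_vs_reference(res_like(5, -0.1), res_like(0, 0))
  expect_equal(out$annotation, "dominated")
})

test_that("net monetary benefit is wtp * qalys - cost", {
  expect_equal(nmb(res_like(0, 0), 20000), 0)
  expect_equal(nmb(res_like(100, 0.01), 20000), 100)
  # at wtp 0 the minimum-cost strategy maximises NMB
  d <- data.frame(strategy = c("A", "B"), cost = c(10, 5), qalys = c(1, 0.1))
  b <- vapply(seq_len(2), function(i) nmb(d[i, ], 0), numeric(1))
  expect_equal(d$strategy[which.max(b)], "B")
})

test_that("frontier identifies strict and extended dominance", {
  # strict dominance: dearer and less effective
  fr <- frontier(data.frame(strategy = c("A", "B"),
                            cost = c(0, 100), qalys = c(0, -0.01)))
  expect_equal(fr$status[fr$strategy == "B"], "dominated")

  # two-point frontier
  fr <- frontier(data.frame(strategy = c("A", "B"),
                            cost = c(0, 100), qalys = c(0, 0.01)))
  expect_equal(fr$icer[fr$strategy == "B"], 10000)
  expect_equal(fr$status, c("reference", "frontier"))

  # worked extended-dominance example: B's ICER vs A (25,000) exceeds
  # C's ICER vs B (1,250), so B is extendedly dominated and C is compared
  # directly with A
  fr <- frontier(make_toy_fixture("frontier3"))
  expect_equal(fr$status[fr$strategy == "B"], "extendedly_dominated")
  expect_equal(sum(fr$status == "extendedly_dominated"), 1)
  expect_equal(fr$icer[fr$strategy == "C"], 6000)
  expect_equal(fr$inc_cost[fr$strategy == "C"], 600)
  expect_equal(fr$inc_qalys[fr$strategy == "C"], 0.10)

  # single strategy: reference only
  fr <- frontier(data.frame(strategy = "A", cost = 5, qalys = 1))
  expect_equal(fr$status, "reference")
})

test_that("frontier is invariant to ordering and duplication", {
  set.seed(7)
  d <- random_strategy_set(5)
  fr1 <- frontier(d)
  fr2 <- frontier(d[sample(nrow(d)), ])
  expect_equal(fr1, fr2)
  dup <- rbind(d, transform(d[2, ], strategy = "S2copy"))
  expect_warning(fr3 <- frontier(dup), "identical cost and QALYs")
  expect_equal(fr3, fr1)
})

test_that("frontier matches brute-force NMB enumeration on random sets", {
  set.seed(123)
  for (rep in 1:200) {
    d <- random_strategy_set(sample(2:6, 1))
    fr <- frontier(d)
    got <- sort(fr$strategy[fr$status %in% c("reference", "frontier")])
    expect_equal(got, frontier_bruteforce(d),
                 info = paste("rep", rep))
    # ICERs strictly increase along the frontier
    icers <- fr$icer[!is.na(fr$icer)]
    if (length(icers) > 1) expect_true(all(diff(icers) > 0))
  }
})

test_that("acceptability curves are exact empirical argmax frequencies", {
  # single strategy: probability 1 everywhere
  d <- data.frame(iter = 1:10, strategy = "A",
                  cost = runif(10), qalys = runif(10))
  cc <- ceac(d, c(0, 20000))
  expect_equal(cc$probability, c(1, 1))

  # non-overlapping NMB distributions: certainty
  d <- rbind(data.frame(iter = 1:50, strategy = "good",
                        cost = runif(50, 0, 10), qalys = runif(50, 1, 2)),
             data.frame(iter = 1:50, strategy = "bad",
                        cost = runif(50, 100, 200), qalys = runif(50, 0, 0.5)))
  cc <- ceac(d, 20000)
  expect_equal(cc$probability[cc$strategy == "good"], 1)
  expect_equal(cc$probability[cc$strategy == "bad"], 0)

  # random draws: match a direct per-iteration recount
  set.seed(11)
  n <- 200
  d <- do.call(rbind, lapply(c("A", "B", "C"), function(s) {
    data.frame(iter = 1:n, strategy = s,
               cost = rnorm(n, 1000, 300), qalys = rnorm(n, 0.5, 0.2))
  }))
  for (w in c(0, 5000, 20000)) {
    cc <- ceac(d, w)
    recount <- sapply(c("A", "B", "C"), function(s) {
      wins <- 0
      for (it in 1:n) {
        sub <- d[d$iter == it, ]
        b <- w * sub$qalys - sub$cost
        if (sub$strategy[which.max(b)] == s) wins <- wins + 1
      }
      wins / n
    })
    expect_equal(stats::setNames(cc$probability, cc$strategy), recount)
    expect_equal(sum(cc$probability), 1, tolerance = 1e-12)
  }

  # mismatched draw counts rejected
  bad <- d[-1, ]
  expect_error(ceac(bad, 20000), "mismatched")
})

test_that("pairwise acceptability compares against a fixed comparator", {
  d <- rbind(data.frame(iter = 1:4, strategy = "A",
                        cost = c(0, 0, 0, 0), qalys = c(1, 1, 0, 0)),
             data.frame(iter = 1:4, strategy = "REF",
                        cost = c(0, 0, 0, 0), qalys = c(0, 0, 1, 1)))
  out <- ceac_pairwise(d, "A", "REF", 10000)
  expect_equal(out$probability, 0.5)
})
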
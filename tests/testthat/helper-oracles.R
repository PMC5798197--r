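# Independent oracles used across the suite. These deliberately avoid the
# package's fast propagation path.

# propagate an initial occupancy vector by explicit matrix products
matrix_trace <- function(arm, init = NULL) {
  h <- arm$globals$horizon_years
  s <- state_names()
  if (is.null(init)) {
    init <- stats::setNames(numeric(length(s)), s)
    init["IH"] <- 1
  }
  occ <- matrix(0, h + 1, length(s), dimnames = list(0:h, s))
  occ[1, ] <- init
  v <- init
  for (t in seq_len(h)) {
    v <- as.numeric(v %*% build_transition_matrix(arm, t))
    occ[t + 1, ] <- v
  }
  occ
}

# brute-force frontier: a strategy is on the cost-effectiveness frontier
# iff it uniquely maximises net monetary benefit at some willingness to
# pay; probe thresholds around every pairwise slope plus extremes
frontier_bruteforce <- function(d) {
  slopes <- c()
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(d))) {
      dq <- d$qalys[j] - d$qalys[i]
      if (dq > 0) slopes <- c(slopes, (d$cost[j] - d$cost[i]) / dq)
    }
  }
  slopes <- slopes[slopes > 0 & is.finite(slopes)]
  probes <- sort(unique(c(1e-9, 1e12,
                          as.vector(outer(slopes, c(0.999, 1.001))))))
  probes <- probes[probes > 0]
  on_frontier <- rep(FALSE, nrow(d))
  for (w in probes) {
    b <- w * d$qalys - d$cost
    winners <- which(b > max(b) - 1e-9 * max(1, abs(max(b))))
    if (length(winners) == 1) on_frontier[winners] <- TRUE
  }
  sort(d$strategy[on_frontier])
}

# random cost/QALY strategy sets for property tests
random_strategy_set <- function(k) {
  data.frame(strategy = paste0("S", seq_len(k)),
             cost = stats::runif(k, 0, 10000),
             qalys = stats::runif(k, 0, 2))
}

# a minimal arm for hand-built dynamics: frozen fixture with overrides
toy_arm <- function(transitions = NULL, q = NULL, horizon = NULL,
                    discount = NULL, payoffs = NULL) {
  arm <- make_toy_fixture("frozen")
  if (!is.null(transitions)) arm$transitions[names(transitions)] <- transitions
  if (!is.null(q)) arm$life_table <- data.frame(age = 50:110, qx = q)
  if (!is.null(horizon)) arm$globals$horizon_years <- as.integer(horizon)
  if (!is.null(discount)) arm$globals$discount_rate <- discount
  if (!is.null(payoffs)) arm$payoffs[names(payoffs)] <- payoffs
  arm
}
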
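as_ce_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("strategy", "cost", "qalys") %in% names(x)))
    return(x[c("strategy", "cost", "qalys")])
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "strategy_result"))) {
    return(do.call(rbind, lapply(unname(x), function(r) {
      data.frame(strategy = r$strategy, cost = r$cost, qalys = r$qalys)
    })))
  }
  stop("expected a data frame with strategy/cost/qalys or a list of strategy_result",
       call. = FALSE)
}

#' Cost-effectiveness ratio versus a fixed reference
#'
#' `(cost - reference cost) / (QALYs - reference QALYs)`. A zero QALY
#' difference is signalled as undefined (`NA` with an annotation) rather
#' than infinity; a negative ratio is returned as-is with a dominance
#' annotation (`"dominant"` when cheaper and more effective,
#' `"dominated"` when dearer and less effective).
#'
#' @param result,reference `strategy_result`s, or lists with `cost` and
#'   `qalys` fields.
#' @return List with `delta_cost`, `delta_qalys`, `cer`, `annotation`.
#' @export
cer_vs_reference <- function(result, reference) {
  dc <- result$cost - reference$cost
  dq <- result$qalys - reference$qalys
  if (dq == 0) {
    return(list(delta_cost = dc, delta_qalys = 0, cer = NA_real_,
                annotation = "undefined (zero QALY difference)"))
  }
  cer <- dc / dq
  annotation <- ""
  if (dc < 0 && dq > 0) annotation <- "dominant"
  if (dc > 0 && dq < 0) annotation <- "dominated"
  list(delta_cost = dc, delta_qalys = dq, cer = cer, annotation = annotation)
}

#' Net monetary benefit
#'
#' @param result A `strategy_result` or list with `cost` and `qalys`.
#' @param wtp Willingness-to-pay threshold, GBP/QALY, >= 0.
#' @return `wtp * qalys - cost`, GBP.
#' @export
nmb <- function(result, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * result$qalys - result$cost
}

#' Cost-effectiveness frontier with strict and extended dominance
#'
#' Orders strategies by cost, removes strictly dominated strategies (at
#' least as costly and no more effective than another, with one relation
#' strict), then iteratively removes extendedly dominated strategies (those
#' whose ICER versus the previous frontier point exceeds the ICER of the
#' next point versus that same predecessor) until ICERs strictly increase
#' along the frontier. Each surviving strategy reports its incremental cost,
#' incremental QALYs and ICER versus the previous survivor; the least
#' costly survivor is the reference. Strategies with identical cost and
#' QALYs are merged with a warning. The result is invariant to input
#' ordering.
#'
#' @param x Data frame with columns `strategy`, `cost`, `qalys`, or a list
#'   of `strategy_result`s.
#' @return Data frame with columns `strategy`, `cost`, `qalys`, `status`
#'   (`reference`, `frontier`, `dominated`, `extendedly_dominated`),
#'   `inc_cost`, `inc_qalys`, `icer`, ordered by cost.
#' @export
frontier <- function(x) {
  d <- as_ce_table(x)
  if (nrow(d) == 0) stop("no strategies supplied", call. = FALSE)
  # merge exact cost/QALY ties
  key <- paste(d$cost, d$qalys)
  if (anyDuplicated(key)) {
    dup <- duplicated(key)
    warning(sprintf("merging strategies with identical cost and QALYs: %s",
                    paste(d$strategy[dup], collapse = ", ")), call. = FALSE)
    d <- d[!dup, , drop = FALSE]
  }
  d <- d[order(d$cost, d$qalys), , drop = FALSE]
  n <- nrow(d)
  status <- rep("frontier", n)
  for (i in seq_len(n)) {
    dominated <- any(d$cost <= d$cost[i] & d$qalys >= d$qalys[i] &
                       (d$cost < d$cost[i] | d$qalys > d$qalys[i]))
    if (dominated) status[i] <- "dominated"
  }
  cand <- which(status == "frontier")
  repeat {
    if (length(cand) <= 2) break
    icers <- diff(d$cost[cand]) / diff(d$qalys[cand])
    bad <- which(diff(icers) <= 0)
    if (!length(bad)) break
    # the interior point whose ICER fails to increase is extendedly dominated
    status[cand[bad[1] + 1L]] <- "extendedly_dominated"
    cand <- which(status == "frontier")
  }
  d$status <- status
  d$inc_cost <- NA_real_
  d$inc_qalys <- NA_real_
  d$icer <- NA_real_
  if (length(cand)) {
    d$status[cand[1]] <- "reference"
    if (length(cand) > 1) {
      prev <- cand[-length(cand)]
      cur <- cand[-1]
      d$inc_cost[cur] <- d$cost[cur] - d$cost[prev]
      d$inc_qalys[cur] <- d$qalys[cur] - d$qalys[prev]
      d$icer[cur] <- d$inc_cost[cur] / d$inc_qalys[cur]
    }
  }
  rownames(d) <- NULL
  d
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which each strategy attains the maximal net monetary benefit among all
#' comparators (ties split equally), i.e. the joint, frontier-style
#' acceptability. Probabilities sum to 1 at every threshold.
#'
#' @param draws Data frame with columns `iter`, `strategy`, `cost`,
#'   `qalys`: one row per strategy per PSA iteration, every strategy
#'   evaluated under the same sampled parameters within an iteration.
#' @param wtp_grid Numeric vector of thresholds (GBP/QALY).
#' @return Data frame with columns `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(draws, wtp_grid) {
  stopifnot(is.data.frame(draws),
            all(c("iter", "strategy", "cost", "qalys") %in% names(draws)))
  counts <- table(draws$strategy)
  if (length(unique(counts)) != 1L) {
    stop("strategies have mismatched PSA draw counts", call. = FALSE)
  }
  strategies <- sort(unique(draws$strategy))
  iters <- sort(unique(draws$iter))
  cost <- matrix(NA_real_, length(iters), length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- cost
  idx_i <- match(draws$iter, iters)
  idx_s <- match(draws$strategy, strategies)
  cost[cbind(idx_i, idx_s)] <- draws$cost
  qaly[cbind(idx_i, idx_s)] <- draws$qalys
  if (anyNA(cost) || anyNA(qaly)) {
    stop("each strategy must appear exactly once per iteration",
         call. = FALSE)
  }
  out <- lapply(wtp_grid, function(w) {
    b <- w * qaly - cost
    best <- b == apply(b, 1, max)
    wins <- best / rowSums(best)  # ties split equally
    data.frame(wtp = w, strategy = strategies,
               probability = colMeans(wins), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Pairwise acceptability versus a reference strategy
#'
#' Probability, over PSA iterations, that `strategy` has higher net
#' monetary benefit than `reference` at each threshold (the probability
#' its ICER versus that comparator is acceptable). Ties count half.
#'
#' @inheritParams ceac
#' @param strategy,reference Strategy labels present in `draws`.
#' @return Data frame with columns `wtp`, `probability`.
#' @export
ceac_pairwise <- function(draws, strategy, reference, wtp_grid) {
  stopifnot(all(c(strategy, reference) %in% draws$strategy))
  a <- draws[draws$strategy == strategy, ]
  b <- draws[draws$strategy == reference, ]
  a <- a[order(a$iter), ]
  b <- b[order(b$iter), ]
  if (!identical(a$iter, b$iter)) {
    stop("strategies have mismatched PSA iterations", call. = FALSE)
  }
  out <- vapply(wtp_grid, function(w) {
    da <- w * a$qalys - a$cost
    db <- w * b$qalys - b$cost
    mean((da > db) + 0.5 * (da == db))
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = out)
}
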
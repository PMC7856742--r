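## Incremental cost-effectiveness analysis: ICERs, the cost-effectiveness
## frontier with strict and extended dominance, and net monetary benefit.

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental effect (QALYs).
#' @return A list: `icer` (USD/QALY, or `NA` when flagged) and `flag`
#'   (`"none"`, `"dominant"` when cheaper and more effective, `"dominated"`
#'   when costlier and less effective, `"undefined"` when the effect
#'   difference is zero).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    return(list(icer = NA_real_, flag = "undefined"))
  }
  if (delta_cost < 0 && delta_qaly > 0) {
    return(list(icer = delta_cost / delta_qaly, flag = "dominant"))
  }
  if (delta_cost > 0 && delta_qaly < 0) {
    return(list(icer = delta_cost / delta_qaly, flag = "dominated"))
  }
  list(icer = delta_cost / delta_qaly, flag = "none")
}

#' Net monetary benefit
#'
#' @param cost Total cost (USD).
#' @param qaly Total QALYs.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return `wtp * qaly - cost`, in USD.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  wtp * qaly - cost
}

#' Cost-effectiveness frontier with dominance handling
#'
#' Sorts strategies by cost, removes strictly dominated strategies (at
#' least as costly as another with no more QALYs), then iteratively removes
#' extendedly dominated strategies (those whose sequential ICER strictly
#' exceeds the next one's; equal sequential ICERs are kept). Each surviving
#' strategy's ICER is reported against the next-cheaper frontier strategy;
#' the preferred strategy is the most effective frontier strategy whose
#' sequential ICER does not exceed the willingness-to-pay threshold.
#' Incremental columns versus the cheapest strategy are also reported,
#' mirroring the conventional base-case table.
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly`.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return Data frame of class `cea_result`, one row per strategy (sorted
#'   by cost): cost, qaly, increments and ICER versus the cheapest
#'   strategy, frontier ICER, `dominance`
#'   (`none`/`dominated`/`extendedly_dominated`), `on_frontier`,
#'   `preferred`. Attribute `preferred` holds the preferred strategy label.
#' @export
frontier <- function(results, wtp = 27931.04) {
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(results)))
  if (nrow(results) < 1) stop("no strategies supplied")
  res <- results[order(results$cost, results$qaly,
                       seq_len(nrow(results))), , drop = FALSE]
  n <- nrow(res)
  dominance <- rep("none", n)

  # strict dominance: another strategy costs no more and yields at least as
  # many QALYs, with at least one strict inequality; identical points are
  # resolved toward the earlier-listed strategy
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cheaper_better <-
        (res$cost[j] < res$cost[i] && res$qaly[j] >= res$qaly[i]) ||
        (res$cost[j] <= res$cost[i] && res$qaly[j] > res$qaly[i])
      duplicate_later <- res$cost[j] == res$cost[i] &&
        res$qaly[j] == res$qaly[i] && j < i
      if (cheaper_better || duplicate_later) dominance[i] <- "dominated"
    }
  }

  # extended dominance on the surviving, cost-sorted sequence
  repeat {
    alive <- which(dominance == "none")
    if (length(alive) < 3) break
    icers <- vapply(seq_along(alive)[-1], function(k) {
      a <- alive[k - 1]; b <- alive[k]
      (res$cost[b] - res$cost[a]) / (res$qaly[b] - res$qaly[a])
    }, numeric(1))
    drop <- which(utils::head(icers, -1) > utils::tail(icers, -1))
    if (length(drop) == 0) break
    dominance[alive[drop[1] + 1]] <- "extendedly_dominated"
  }

  alive <- which(dominance == "none")
  front_icer <- rep(NA_real_, n)
  if (length(alive) > 1) {
    for (k in seq_along(alive)[-1]) {
      a <- alive[k - 1]; b <- alive[k]
      front_icer[b] <- (res$cost[b] - res$cost[a]) /
        (res$qaly[b] - res$qaly[a])
    }
  }

  # preferred: most effective frontier strategy with sequential ICER <= wtp
  preferred_idx <- alive[1]
  for (k in seq_along(alive)[-1]) {
    if (front_icer[alive[k]] <= wtp) preferred_idx <- alive[k]
  }

  base <- 1  # cheapest strategy as the common comparator
  inc_cost <- res$cost - res$cost[base]
  inc_qaly <- res$qaly - res$qaly[base]
  icer_vs_base <- ifelse(inc_qaly == 0, NA_real_, inc_cost / inc_qaly)
  icer_vs_base[base] <- NA_real_

  out <- data.frame(
    strategy = res$strategy,
    cost = res$cost,
    qaly = res$qaly,
    inc_cost = ifelse(seq_len(n) == base, NA_real_, inc_cost),
    inc_qaly = ifelse(seq_len(n) == base, NA_real_, inc_qaly),
    icer_vs_base = icer_vs_base,
    frontier_icer = front_icer,
    dominance = dominance,
    on_frontier = dominance == "none",
    preferred = seq_len(n) == preferred_idx,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("cea_result", "data.frame")
  attr(out, "preferred") <- res$strategy[preferred_idx]
  attr(out, "wtp") <- wtp
  out
}
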
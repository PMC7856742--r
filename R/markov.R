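## Discounted Markov cohort model. Four clinical states (disease-free,
## local recurrence, distant metastasis, death) with the first year of
## disease-free survival and of local recurrence encoded as single-cycle
## tunnel states, so that first-year costs and utilities differ from
## subsequent years. Cycle length is one year; the cohort starts entirely
## in the first disease-free year.

#' Model states
#'
#' `DFS_Y1` and `LR_Y1` are single-cycle tunnel states carrying the
#' first-year costs/utilities of disease-free survival and local
#' recurrence; `DFS_PLUS` and `LR_PLUS` are the corresponding
#' subsequent-year states; `MET` is distant metastasis and `DEATH` the
#' absorbing death state.
#'
#' @return Character vector of the six state names.
#' @export
model_states <- function() {
  c("DFS_Y1", "DFS_PLUS", "LR_Y1", "LR_PLUS", "MET", "DEATH")
}

#' Build a strategy's transition matrix
#'
#' Both disease-free states share the annual exit probabilities to the
#' local-recurrence tunnel and to metastasis; both local-recurrence states
#' exit to metastasis with the same annual probability (remainder advancing
#' to, or staying in, `LR_PLUS`); metastasis exits to death with the annual
#' breast-cancer death probability; death is absorbing. Direct death from
#' disease-free or recurrent states occurs only through the optional
#' background other-cause mortality (see [run_cohort()]).
#'
#' @param ts A `transition_set` (all strategies) or a one-row subset.
#' @param strategy Strategy label to extract from `ts`.
#' @return A 6x6 row-stochastic matrix over [model_states()].
#' @export
build_matrix <- function(ts, strategy) {
  row <- ts[ts$strategy == strategy, , drop = FALSE]
  if (nrow(row) != 1) stop("no transition row for strategy ", strategy)
  p_lr <- row$p_dfs_to_lr
  p_met <- row$p_dfs_to_met
  p_lrmet <- row$p_lr_to_met
  p_death <- row$p_met_to_death
  if (p_lr + p_met > 1) stop("DFS exit probabilities sum above 1")
  if (any(c(p_lr, p_met, p_lrmet, p_death) < 0) ||
      any(c(p_lrmet, p_death) > 1)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  st <- model_states()
  P <- matrix(0, 6, 6, dimnames = list(st, st))
  P["DFS_Y1", "LR_Y1"] <- p_lr
  P["DFS_Y1", "MET"] <- p_met
  P["DFS_Y1", "DFS_PLUS"] <- 1 - p_lr - p_met
  P["DFS_PLUS", "LR_Y1"] <- p_lr
  P["DFS_PLUS", "MET"] <- p_met
  P["DFS_PLUS", "DFS_PLUS"] <- 1 - p_lr - p_met
  P["LR_Y1", "MET"] <- p_lrmet
  P["LR_Y1", "LR_PLUS"] <- 1 - p_lrmet
  P["LR_PLUS", "MET"] <- p_lrmet
  P["LR_PLUS", "LR_PLUS"] <- 1 - p_lrmet
  P["MET", "DEATH"] <- p_death
  P["MET", "MET"] <- 1 - p_death
  P["DEATH", "DEATH"] <- 1
  stopifnot(all(abs(rowSums(P) - 1) < 1e-12))
  P
}

# Competitive overlay of a per-cycle other-cause death probability q:
# every living state's transitions are scaled by (1 - q) and q is routed
# to DEATH.
apply_background_mortality <- function(P, q) {
  if (q <= 0) return(P)
  living <- setdiff(rownames(P), "DEATH")
  P[living, ] <- P[living, ] * (1 - q)
  P[living, "DEATH"] <- P[living, "DEATH"] + q
  P
}

#' Run the discounted cohort simulation for one strategy
#'
#' Iterates the cohort occupancy for `n_cycles` annual cycles and
#' accumulates discounted cost and QALY streams. State rewards (annual
#' state costs and utilities) accrue, under half-cycle correction, on the
#' average of start- and end-of-cycle occupancy; one-time rewards (the
#' three-months-before-death cost on the metastasis-to-death flow) accrue
#' on the transition flow of the cycle and are not half-cycle corrected.
#' Cycle `t` rewards are discounted by `(1 + rate)^-t`, first cycle at
#' `t = 1`.
#'
#' @param P Transition matrix from [build_matrix()].
#' @param costs One strategy's component of a `cost_schedule`
#'   (see [assemble_cost_schedule()]).
#' @param utilities One strategy's component of a `utility_set`.
#' @param settings An `econ_settings` object.
#' @param init Initial occupancy over [model_states()] (default: all in
#'   `DFS_Y1`).
#' @param cycle_eval Occupancy used for state rewards: `"half-cycle"`
#'   (default when `settings$half_cycle_correction` is `TRUE`), `"start"`
#'   or `"end"` of cycle. When `settings$half_cycle_correction` is `FALSE`
#'   the default is `"end"`.
#' @param background_mortality Optional numeric vector (length `n_cycles`)
#'   of per-cycle other-cause death probabilities, applied competitively to
#'   every living state. Default `NULL` (off): the published model inputs
#'   carry no life table, so the default model has no other-cause death.
#' @return Data frame of class `markov_trace`: per cycle, occupancy of the
#'   six states, undiscounted and discounted cycle cost and QALY, and
#'   cumulative discounted totals (attributes `total_cost`, `total_qaly`).
#' @export
run_cohort <- function(P, costs, utilities, settings = econ_settings(),
                       init = NULL, cycle_eval = NULL,
                       background_mortality = NULL) {
  st <- model_states()
  if (is.null(init)) {
    init <- stats::setNames(c(1, 0, 0, 0, 0, 0), st)
  }
  stopifnot(length(init) == 6, abs(sum(init) - 1) < 1e-8)
  if (is.null(cycle_eval)) {
    cycle_eval <- if (settings$half_cycle_correction) "half-cycle" else "end"
  }
  cycle_eval <- match.arg(cycle_eval, c("half-cycle", "start", "end"))
  n <- settings$n_cycles
  if (!is.null(background_mortality)) {
    stopifnot(length(background_mortality) == n,
              all(background_mortality >= 0),
              all(background_mortality <= 1))
  }
  state_cost <- c(costs$dfs_y1, costs$dfs_plus, costs$lr_y1, costs$lr_plus,
                  costs$met, 0)
  state_util <- c(utilities$dfs_y1, utilities$dfs_plus, utilities$lr_y1,
                  utilities$lr_plus, utilities$met, utilities$death)
  disc <- (1 + settings$discount_rate)^-(seq_len(n))
  occ <- matrix(0, n, 6, dimnames = list(NULL, st))
  cost_cycle <- qaly_cycle <- numeric(n)
  x <- init
  for (t in seq_len(n)) {
    Pt <- if (is.null(background_mortality)) P else
      apply_background_mortality(P, background_mortality[t])
    x_new <- as.vector(x %*% Pt)
    names(x_new) <- st
    x_eval <- switch(cycle_eval,
                     "half-cycle" = (x + x_new) / 2,
                     "start" = x,
                     "end" = x_new)
    # disease-driven death flow this cycle (carries the pre-death cost)
    death_flow <- x[["MET"]] * P["MET", "DEATH"] *
      (if (is.null(background_mortality)) 1 else
        (1 - background_mortality[t]))
    cost_cycle[t] <- sum(x_eval * state_cost) +
      death_flow * costs$death_transition
    qaly_cycle[t] <- sum(x_eval * state_util)
    occ[t, ] <- x_new
    x <- x_new
  }
  trace <- data.frame(cycle = seq_len(n), occ,
                      cost = cost_cycle, qaly = qaly_cycle,
                      disc_cost = cost_cycle * disc,
                      disc_qaly = qaly_cycle * disc)
  trace$cum_cost <- cumsum(trace$disc_cost)
  trace$cum_qaly <- cumsum(trace$disc_qaly)
  class(trace) <- c("markov_trace", "data.frame")
  attr(trace, "total_cost") <- sum(trace$disc_cost)
  attr(trace, "total_qaly") <- sum(trace$disc_qaly)
  trace
}

#' Lifetime discounted cost and QALYs per strategy
#'
#' Runs the cohort model for all three strategies under identical settings
#' and returns total discounted cost and QALYs for each.
#'
#' @param params A validated `param_set`.
#' @param settings An `econ_settings`; its discount rate is overridden by
#'   the parameter set's `discount_rate` entry (so sensitivity analyses that
#'   perturb the entry propagate).
#' @param transitions Optional `transition_set` replacing the parameter
#'   set's transition entries (e.g. estimated from patient-level data).
#' @param background_mortality Optional per-cycle other-cause death
#'   probability vector (see [run_cohort()]).
#' @param lr_plus_costs,lr_plus_utility Conventions for recurrence years
#'   beyond the first, passed to [assemble_cost_schedule()] and
#'   [utility_set()].
#' @return Data frame: `strategy`, `cost`, `qaly`; the full traces are
#'   attached as attribute `traces`.
#' @export
strategy_outcomes <- function(params, settings = econ_settings(),
                              transitions = NULL,
                              background_mortality = NULL,
                              lr_plus_costs = "followup",
                              lr_plus_utility = "dfs_plus") {
  settings$discount_rate <- param_value(params, "discount_rate")
  costs <- assemble_cost_schedule(params, lr_plus = lr_plus_costs)
  utils_ <- utility_set(params, lr_plus = lr_plus_utility)
  if (is.null(transitions)) transitions <- transition_set(params)
  traces <- lapply(strategies(), function(s) {
    P <- build_matrix(transitions, s)
    run_cohort(P, costs[[s]], utils_[[s]], settings,
               background_mortality = background_mortality)
  })
  names(traces) <- strategies()
  out <- data.frame(
    strategy = strategies(),
    cost = vapply(traces, attr, numeric(1), which = "total_cost"),
    qaly = vapply(traces, attr, numeric(1), which = "total_qaly"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "traces") <- traces
  out
}
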
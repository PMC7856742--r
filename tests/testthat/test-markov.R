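zero_ts <- function() {
  ts <- data.frame(strategy = strategies(), p_dfs_to_lr = 0,
                   p_dfs_to_met = 0, p_lr_to_met = 0, p_met_to_death = 0)
  class(ts) <- c("transition_set", "data.frame")
  ts
}

flat_costs <- function(x = 0) {
  list(dfs_y1 = x, dfs_plus = x, lr_y1 = x, lr_plus = x, met = x,
       death_transition = x)
}

flat_utils <- function(u = 1) {
  list(dfs_y1 = u, dfs_plus = u, lr_y1 = u, lr_plus = u, met = u, death = 0)
}

test_that("transition matrices encode the model structure", {
  p <- load_parameters()
  ts <- transition_set(p)
  for (s in strategies()) {
    P <- build_matrix(ts, s)
    expect_equal(rowSums(P), setNames(rep(1, 6), model_states()),
                 tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(P["DEATH", ]), c(0, 0, 0, 0, 0, 1))
    # tunnels: both disease-free states share exits, as do both LR states
    expect_equal(P["DFS_Y1", "LR_Y1"], P["DFS_PLUS", "LR_Y1"])
    expect_equal(P["DFS_Y1", "MET"], P["DFS_PLUS", "MET"])
    expect_equal(P["LR_Y1", "MET"], P["LR_PLUS", "MET"])
  }
  # mastectomy: recurrence converts to metastasis with certainty, so the
  # beyond-first-year recurrence state is unreachable
  P_mast <- build_matrix(ts, "MAST")
  expect_equal(P_mast["LR_Y1", "MET"], 1)
  expect_equal(P_mast["LR_Y1", "LR_PLUS"], 0)

  # all-zero transitions: identity dynamics except tunnel advance
  P0 <- build_matrix(zero_ts(), "BCT")
  expect_equal(P0["DFS_Y1", "DFS_PLUS"], 1)
  expect_equal(P0["LR_Y1", "LR_PLUS"], 1)
  expect_equal(P0["MET", "MET"], 1)

  bad <- zero_ts(); bad$p_dfs_to_lr <- 0.7; bad$p_dfs_to_met <- 0.5
  expect_error(build_matrix(bad, "MAST"), "sum above 1")
  expect_error(build_matrix(ts, "LUMPECTOMY"), "no transition row")
})

test_that("the degenerate cohort reproduces the discounted annuity", {
  u <- 0.9; d <- 0.03; n <- 60
  set <- econ_settings(discount_rate = d, n_cycles = n,
                       half_cycle_correction = FALSE)
  P <- build_matrix(zero_ts(), "MAST")
  tr <- run_cohort(P, flat_costs(0), flat_utils(u), set)
  expect_equal(attr(tr, "total_qaly"), u * sum((1 + d)^-(1:n)),
               tolerance = 1e-12)
  expect_equal(attr(tr, "total_cost"), 0)

  # all utilities one, no death, no discounting: QALY equals the horizon
  set0 <- econ_settings(discount_rate = 0, n_cycles = 60,
                        half_cycle_correction = FALSE)
  tr0 <- run_cohort(P, flat_costs(0), flat_utils(1), set0)
  expect_equal(attr(tr0, "total_qaly"), 60, tolerance = 1e-12)

  # one undiscounted cycle spent fully in metastasis costs one annual cycle
  set1 <- econ_settings(discount_rate = 0, n_cycles = 1,
                        half_cycle_correction = FALSE)
  init <- setNames(c(0, 0, 0, 0, 1, 0), model_states())
  costs <- flat_costs(0); costs$met <- 10652.42 + 2984.55
  tr1 <- run_cohort(P, costs, flat_utils(0.737), set1, init = init)
  expect_equal(attr(tr1, "total_cost"), 13636.97)
})

test_that("occupancy is conserved and the trace is monotone", {
  p <- load_parameters()
  ts <- transition_set(p)
  cs <- assemble_cost_schedule(p)
  us <- utility_set(p)
  for (s in strategies()) {
    tr <- run_cohort(build_matrix(ts, s), cs[[s]], us[[s]], econ_settings())
    occ <- as.matrix(tr[, model_states()])
    expect_lt(max(abs(rowSums(occ) - 1)), 1e-10)
    expect_true(all(diff(tr$cum_cost) >= 0))
    expect_true(all(diff(tr$cum_qaly) >= 0))
    expect_true(all(diff(tr$DEATH) >= -1e-12))  # absorbing
  }
})

test_that("rewards respond monotonically to their parameters", {
  p <- load_parameters()
  base <- strategy_outcomes(p)
  up_util <- strategy_outcomes(
    load_parameters(overrides = list("utility_dfs_plus:BCT" = 0.98)))
  expect_gt(up_util$qaly[up_util$strategy == "BCT"],
            base$qaly[base$strategy == "BCT"])
  expect_equal(up_util$qaly[up_util$strategy == "MAST"],
               base$qaly[base$strategy == "MAST"])
  more_death <- strategy_outcomes(
    load_parameters(overrides = list("p_met_to_death:BCT" = 0.08)))
  expect_lt(more_death$qaly[more_death$strategy == "BCT"],
            base$qaly[base$strategy == "BCT"])
})

test_that("half-cycle correction lies between start and end evaluation", {
  p <- load_parameters()
  ts <- transition_set(p)
  cs <- assemble_cost_schedule(p)
  us <- utility_set(p)
  set <- econ_settings()
  for (s in strategies()) {
    P <- build_matrix(ts, s)
    tot <- sapply(c("start", "half-cycle", "end"), function(ev)
      attr(run_cohort(P, cs[[s]], us[[s]], set, cycle_eval = ev),
           "total_qaly"))
    expect_lte(tot[["half-cycle"]], tot[["start"]] + 1e-12)
    expect_gte(tot[["half-cycle"]], tot[["end"]] - 1e-12)
    expect_equal(tot[["half-cycle"]], (tot[["start"]] + tot[["end"]]) / 2)
  }
})

test_that("total cost scales linearly in the cost parameters", {
  p <- load_parameters()
  doubled_path <- write_params_csv(function(df) {
    cost_rows <- grepl("^cost_", df$id)
    df$baseline[cost_rows] <- 2 * df$baseline[cost_rows]
    df$lower[cost_rows] <- 2 * df$lower[cost_rows]
    df$upper[cost_rows] <- 2 * df$upper[cost_rows]
    df
  })
  base <- strategy_outcomes(p)
  twice <- strategy_outcomes(load_parameters(doubled_path))
  expect_equal(twice$cost, 2 * base$cost, tolerance = 1e-10)
  expect_equal(twice$qaly, base$qaly, tolerance = 1e-12)
})

test_that("optional background mortality drains every living state", {
  p <- load_parameters()
  set <- econ_settings()
  bg <- rep(0.01, set$n_cycles)
  base <- strategy_outcomes(p, set)
  with_bg <- strategy_outcomes(p, set, background_mortality = bg)
  expect_true(all(with_bg$qaly < base$qaly))
  expect_true(all(with_bg$cost < base$cost))
  tr <- attr(with_bg, "traces")$MAST
  expect_lt(max(abs(rowSums(as.matrix(tr[, model_states()])) - 1)), 1e-10)
  # even the all-zero transition model now reaches death
  trace0 <- run_cohort(build_matrix(zero_ts(), "MAST"), flat_costs(),
                       flat_utils(), set, background_mortality = bg)
  expect_gt(trace0$DEATH[set$n_cycles], 0.4)
})

test_that("the base case reproduces the published orderings and frontier", {
  p <- load_parameters()
  out <- strategy_outcomes(p)
  cost <- setNames(out$cost, out$strategy)
  qaly <- setNames(out$qaly, out$strategy)
  expect_true(cost[["BCT"]] > cost[["MAST_RECON"]])
  expect_true(cost[["MAST_RECON"]] > cost[["MAST"]])
  expect_true(qaly[["BCT"]] > qaly[["MAST_RECON"]])
  expect_true(qaly[["MAST_RECON"]] > qaly[["MAST"]])
  fr <- frontier(out, wtp = 27931.04)
  expect_identical(attr(fr, "preferred"), "BCT")
  expect_identical(fr$dominance[fr$strategy == "MAST_RECON"],
                   "extendedly_dominated")
  expect_lt(fr$icer_vs_base[fr$strategy == "BCT"], 27931.04)
})
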
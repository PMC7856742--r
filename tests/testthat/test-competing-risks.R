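test_that("cumulative incidence matches the hand-tabulated product-sum", {
  # subjects at t = 1, 2, 3, 4 with event, competing, event, censored:
  # CIF_event = 1/4 at t=1; unchanged at t=2; + S(2-) * 1/2 = 1/2 at t=3
  cv <- cumulative_incidence(c(1, 2, 3, 4), c(1, 2, 1, 0))
  ev <- cv[cv$event_type == "event", ]
  expect_equal(ev$time, 1:4)
  expect_equal(ev$estimate, c(0.25, 0.25, 0.50, 0.50))
  cp <- cv[cv$event_type == "competing", ]
  expect_equal(cp$estimate, c(0, 0.25, 0.25, 0.25))
  expect_equal(ev$at_risk, c(4, 3, 2, 1))
})

test_that("with no competing events the CIF reduces to 1 - Kaplan-Meier", {
  set.seed(12)
  tm <- round(rexp(60, 0.1), 3) + 0.001
  st <- rbinom(60, 1, 0.7)
  cv <- cumulative_incidence(tm, st)
  km <- survival::survfit(survival::Surv(tm, st) ~ 1)
  ev <- cv[cv$event_type == "event", ]
  expect_equal(ev$estimate, 1 - km$surv, tolerance = 1e-12)
})

test_that("CIF is scale-invariant, additive, and agrees with cmprsk", {
  set.seed(13)
  n <- 150
  tm <- round(rexp(n, 0.2), 3) + 0.001
  st <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  cv <- cumulative_incidence(tm, st)
  # duplicating the dataset leaves the curve unchanged
  cv2 <- cumulative_incidence(c(tm, tm), c(st, st))
  expect_equal(cv2$estimate[cv2$event_type == "event"],
               cv$estimate[cv$event_type == "event"])
  # additivity: 1 - KM(all causes) = sum of cause-specific CIFs
  km <- survival::survfit(survival::Surv(tm, pmin(st, 1)) ~ 1)
  total <- cv$estimate[cv$event_type == "event"] +
    cv$estimate[cv$event_type == "competing"]
  expect_equal(total, 1 - km$surv, tolerance = 1e-12)
  expect_true(all(diff(cv$estimate[cv$event_type == "event"]) >= -1e-12))
  expect_true(all(total <= 1 + 1e-12))
  # independent implementation: cmprsk::cuminc at the event times
  ci <- cmprsk::cuminc(tm, st, cencode = 0)
  tp <- cmprsk::timepoints(ci, sort(unique(tm)))$est
  expect_equal(unname(cv$estimate[cv$event_type == "event"]),
               unname(tp["1 1", ]), tolerance = 1e-8)

  expect_error(cumulative_incidence(c(-1, 2), c(1, 1)), "non-negative")
  flat <- cumulative_incidence(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(flat$estimate == 0))
})

test_that("the permutation Gray test matches exact enumeration", {
  # identical duplicated groups: no CIF difference, p = 1
  tm <- c(1, 2, 3, 4, 5); st <- c(1, 2, 0, 1, 0)
  gt0 <- gray_test(c(tm, tm), c(st, st), rep(c("a", "b"), each = 5))
  expect_true(gt0$exact)
  expect_lt(gt0$statistic, 1e-10)
  expect_equal(gt0$p_value, 1)

  # 6-subject toy: exact tail computed independently over all 20 splits
  tm6 <- c(1, 2, 3, 4, 5, 6); st6 <- c(1, 1, 0, 2, 1, 0)
  gp6 <- c("a", "a", "a", "b", "b", "b")
  gt <- gray_test(tm6, st6, gp6)
  expect_true(gt$exact)
  splits <- utils::combn(6, 3)
  stats <- apply(splits, 2, function(ix) {
    g <- rep("b", 6); g[ix] <- "a"
    cmprsk::cuminc(tm6, st6, g, cencode = 0)$Tests["1", "stat"]
  })
  expect_equal(gt$p_value, mean(stats >= gt$statistic - 1e-12))

  expect_error(gray_test(tm6, st6, rep("a", 6)), "at least two groups")
})

test_that("the Gray test detects a threefold hazard difference", {
  set.seed(17)
  n <- 400
  # each group: cause-1 vs cause-2 competing exponentials, uniform censoring
  make_group <- function(r1, r2) {
    e1 <- rexp(n, r1); e2 <- rexp(n, r2)
    cens <- runif(n, 5, 15)
    tt <- pmin(e1, e2, cens)
    ss <- ifelse(tt == cens, 0, ifelse(e1 < e2, 1, 2))
    list(t = tt, s = ss)
  }
  g1 <- make_group(0.30, 0.10)
  g2 <- make_group(0.10, 0.10)
  gt <- gray_test(c(g1$t, g2$t), c(g1$s, g2$s),
                  rep(c("hi", "lo"), each = n), n_perm = 500, seed = 3)
  expect_false(gt$exact)
  expect_lt(gt$p_value, 0.05)
  # determinism given the seed
  gt_b <- gray_test(c(g1$t, g2$t), c(g1$s, g2$s),
                    rep(c("hi", "lo"), each = n), n_perm = 500, seed = 3)
  expect_identical(gt$p_value, gt_b$p_value)
})

test_that("incidence-to-probability conversion matches the worked example", {
  # cumulative recurrence incidence 0.031 over 94 months, annual cycle
  p <- annual_probability(0.031, 94 / 12)
  expect_equal(p, 0.004019, tolerance = 0.005)
  expect_equal(p, 1 - exp(log(1 - 0.031) / (94 / 12)), tolerance = 1e-12)
  expect_equal(annual_probability(0, 5), 0)
  # round-trip identity when the spans agree
  expect_equal(annual_probability(0.37, 3, 3), 0.37, tolerance = 1e-12)
  expect_error(annual_probability(1, 5), "p1")

  # monotonicity: increasing in P1 and t2, decreasing in t1
  p1 <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(annual_probability(p1, 5)) > 0))
  expect_true(all(diff(sapply(1:6, function(t2)
    annual_probability(0.3, 8, t2))) > 0))
  expect_true(all(diff(sapply(2:9, function(t1)
    annual_probability(0.3, t1))) < 0))

  # rate/probability round trip at machine precision
  pr <- c(1e-6, 0.004019, 0.31, 0.99)
  expect_equal(rate_to_prob(prob_to_rate(pr)), pr, tolerance = 1e-12)
  expect_error(prob_to_rate(1.2), "p")
  expect_error(rate_to_prob(-0.1), "non-negative")
})

test_that("transition sets are recovered from CIF curves", {
  # a curve reaching CIF 0.031 at 94 months reproduces the worked example
  curve <- data.frame(group = "MAST", event_type = "event",
                      time = c(40, 94), estimate = c(0.015, 0.031),
                      std_err = c(0.004, 0.006), at_risk = c(100, 10))
  empty_like <- function(g) data.frame(group = g, event_type = "event",
                                       time = 94, estimate = 0, std_err = 0,
                                       at_risk = 10)
  fill <- rbind(empty_like("MAST_RECON"), empty_like("BCT"))
  curves <- list(dfs_lr = rbind(curve, fill), dfs_met = fill,
                 lr_met = fill, met_death = fill)
  ts <- derive_transition_set(curves)
  expect_equal(ts$p_dfs_to_lr[ts$strategy == "MAST"],
               annual_probability(0.031, 94 / 12))
  expect_equal(ts$p_dfs_to_lr[ts$strategy == "BCT"], 0)
  expect_equal(ts$p_met_to_death, rep(0, 3))
  expect_error(derive_transition_set(curves[-1]), "dfs_lr")
  expect_error(derive_transition_set(c(curves[-1], list(dfs_lr = curve[0, ]))),
               "empty")
})

test_that("the estimation pipeline recovers its generating probabilities", {
  p <- load_parameters()
  truth <- transition_set(p)
  coh <- generate_cohort(n_per_group = c(MAST = 4000, MAST_RECON = 4000,
                                         BCT = 4000), seed = 7)
  pat <- simulate_events(coh, hazard_spec(truth, admin_censor = 94), seed = 7)
  est <- estimate_transitions(pat)
  # the dominant disease-free transitions recover within 15%
  for (s in strategies()) {
    expect_lt(abs(est$p_dfs_to_met[est$strategy == s] /
                    truth$p_dfs_to_met[truth$strategy == s] - 1), 0.15)
  }
  # degenerate truths are reproduced at the boundary
  expect_lt(est$p_lr_to_met[est$strategy == "MAST_RECON"], 0.005)
  expect_gt(est$p_lr_to_met[est$strategy == "MAST"], 0.95)
})
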
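test_that("propensity model recovers group shares and saturated frequencies", {
  # no covariate signal: fitted probabilities approximate the group shares
  set.seed(71)
  n <- 600
  pat <- data.frame(patient_id = 1:n,
                    age = rnorm(n, 39, 7),
                    bmi_category = sample(c("underweight", "normal",
                                            "overweight"), n, replace = TRUE),
                    strategy = rep(strategies(), times = c(300, 120, 180)),
                    stringsAsFactors = FALSE)
  sc <- estimate_propensity(pat, covariates = c("age", "bmi_category"))
  expect_equal(dim(sc$probs), c(n, 3))
  expect_equal(unname(rowSums(sc$probs)), rep(1, n), tolerance = 1e-8)
  shares <- c(MAST = 0.5, MAST_RECON = 0.2, BCT = 0.3)
  for (s in strategies()) {
    expect_lt(max(abs(sc$probs[, s] - shares[[s]])), 0.08)
  }

  # saturated two-group toy: fitted probabilities equal cell frequencies
  toy <- data.frame(patient_id = 1:6,
                    x = c("a", "a", "b", "a", "b", "b"),
                    strategy = c("MAST", "MAST", "MAST", "BCT", "BCT", "BCT"),
                    stringsAsFactors = FALSE)
  sc2 <- estimate_propensity(toy, covariates = "x")
  # P(MAST | x = a) = 2/3, P(MAST | x = b) = 1/3
  expect_equal(unname(sc2$probs[1, "MAST"]), 2 / 3, tolerance = 1e-3)
  expect_equal(unname(sc2$probs[3, "MAST"]), 1 / 3, tolerance = 1e-3)
})

test_that("degenerate propensity inputs raise informative errors", {
  pat <- data.frame(patient_id = 1:10, age = rnorm(10, 39, 5),
                    strategy = rep("MAST", 10), stringsAsFactors = FALSE)
  expect_error(estimate_propensity(pat, covariates = "age"),
               "at least two strategies")
  pat2 <- data.frame(patient_id = 1:10, age = rep(39, 10),
                     strategy = rep(c("MAST", "BCT"), 5),
                     stringsAsFactors = FALSE)
  expect_error(estimate_propensity(pat2, covariates = "age"), "constant")
  expect_error(estimate_propensity(pat2, covariates = "weight"), "absent")
})

test_that("greedy nearest-neighbour matching pairs as expected", {
  sc <- fake_scores(ref_lp = c(0.1, 0.5, 0.9),
                    comp_lp = c(0.11, 0.49, 0.88))
  ms <- match_nearest(sc, reference = "MAST_RECON")
  got <- ms$pairs[order(ms$pairs$reference_id), ]
  # brute-force minimal assignment over all 6 permutations gives the same pairs
  bf <- brute_force_assignment(c(0.1, 0.5, 0.9), c(0.11, 0.49, 0.88))
  expect_equal(got$matched_id, 3 + bf$assignment)
  expect_equal(got$matched_id, c(4, 5, 6))
  expect_equal(nrow(ms$matched), 6)

  # identical scores: zero total distance
  sc0 <- fake_scores(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))
  ms0 <- match_nearest(sc0, reference = "MAST_RECON")
  expect_equal(sum(ms0$pairs$distance), 0)

  # matched size contract and shortfall error
  sc_small <- fake_scores(c(0.1, 0.2, 0.3), c(0.15, 0.25))
  expect_error(match_nearest(sc_small, reference = "MAST_RECON"),
               "smaller than reference")
})

test_that("greedy matching equals the optimal assignment on separated scores", {
  set.seed(55)
  for (rep in 1:20) {
    centers <- sort(runif(3, -3, 3))
    if (min(diff(centers)) < 1) next  # keep clusters separated
    ref <- centers + runif(3, -0.1, 0.1)
    comp <- centers + runif(3, -0.1, 0.1)
    sc <- fake_scores(ref, comp)
    ms <- match_nearest(sc, reference = "MAST_RECON")
    bf <- brute_force_assignment(ref, comp)
    expect_equal(sum(ms$pairs$distance), bf$total, tolerance = 1e-10)
  }
  # on arbitrary instances greedy can only do as well or worse
  for (rep in 1:20) {
    ref <- runif(3); comp <- runif(3)
    ms <- match_nearest(fake_scores(ref, comp), reference = "MAST_RECON")
    expect_gte(sum(ms$pairs$distance),
               brute_force_assignment(ref, comp)$total - 1e-12)
  }
})

test_that("matching is a bijection without replacement", {
  coh <- confounded_cohort()
  sc <- estimate_propensity(coh)
  ms <- match_nearest(sc)
  n_ref <- sum(coh$strategy == "MAST_RECON")
  expect_equal(table(ms$matched$strategy)[strategies()] |> unname() |>
                 as.integer(), rep(n_ref, 3))
  # no comparison patient used twice
  expect_false(any(duplicated(ms$pairs$matched_id)))
  # removing matched comparison patients and re-matching yields disjoint pairs
  used <- ms$pairs$matched_id
  rest <- coh[!(coh$patient_id %in% used), ]
  sc2 <- estimate_propensity(rest)
  ms2 <- match_nearest(sc2)
  expect_length(intersect(ms2$pairs$matched_id, used), 0)
})

test_that("balance diagnostics match textbook formulas", {
  # identical groups: all SMDs zero
  base <- data.frame(patient_id = 1:40, age = rep(rnorm(20, 39, 5), 2),
                     bmi_category = rep(sample(c("normal", "overweight"), 20,
                                               replace = TRUE), 2),
                     strategy = rep(c("MAST", "BCT"), each = 20),
                     stringsAsFactors = FALSE)
  bt <- balance_table(base, base, covariates = c("age", "bmi_category"))
  expect_equal(bt$smd_pre, c(0, 0))

  # hand-built 2x3 contingency table: p-value from the textbook chi-square
  counts <- matrix(c(20, 30, 10, 25, 15, 20), nrow = 2, byrow = TRUE,
                   dimnames = list(c("MAST", "BCT"),
                                   c("left", "right", "double")))
  rows <- data.frame(
    patient_id = seq_len(sum(counts)),
    lesion_location = rep(rep(colnames(counts), 2), as.vector(t(counts))),
    strategy = rep(rownames(counts), rowSums(counts)),
    stringsAsFactors = FALSE
  )
  bt2 <- balance_table(rows, rows, covariates = "lesion_location")
  O <- counts
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  expect_equal(bt2$p_pre, stats::pchisq(stat, df = 2, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(balance_table(base, base, covariates = "histology"), "absent")
})

test_that("matching removes the induced confounding", {
  coh <- confounded_cohort()
  sc <- estimate_propensity(coh)
  ms <- match_nearest(sc)
  expect_gte(sum(coh$strategy == "MAST_RECON"), 150)
  bt <- balance_table(coh, ms)
  expect_lt(max(bt$smd_post), max(bt$smd_pre))
  # the dominant confounder (age) ends up below the 0.1 convention and the
  # other strong confounder (BMI class) loses most of its imbalance
  age <- bt[bt$covariate == "age", ]
  bmi <- bt[bt$covariate == "bmi_category", ]
  expect_lt(age$smd_post, 0.1)
  expect_lt(bmi$smd_post, bmi$smd_pre / 2)
  # the balanced table shows no significant differences on either
  expect_gt(age$p_post, 0.05)
  expect_gt(bmi$p_post, 0.05)
  expect_lt(age$p_pre, 0.001)  # the confounding was real before matching
})
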
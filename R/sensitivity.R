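## One-way (tornado) and probabilistic sensitivity analysis over the
## parameter set, with cost-effectiveness acceptability curves.

set_param <- function(params, id, strategy, value) {
  row <- which(params$id == id & params$strategy == strategy)
  stopifnot(length(row) == 1)
  params$baseline[row] <- value
  params
}

#' One-way sensitivity of an ICER to a single parameter
#'
#' Re-runs the full model with the parameter set to each of its bounds
#' (all other parameters at baseline) and records the comparison's ICER at
#' both bounds.
#'
#' @param params A validated `param_set`.
#' @param id,strategy Parameter to vary (strategy `""` for shared entries).
#' @param comparison Character pair `c(intervention, comparator)` whose
#'   ICER is tracked (default breast-conserving therapy vs mastectomy).
#' @param settings An `econ_settings`.
#' @return One-row data frame: parameter key, ICER at the lower and upper
#'   bound, and the tornado bar `width` (absolute ICER difference).
#' @export
one_way <- function(params, id, strategy = "",
                    comparison = c("BCT", "MAST"),
                    settings = econ_settings()) {
  entry <- param_entry(params, id, strategy)
  icer_for <- function(value) {
    res <- strategy_outcomes(set_param(params, id, strategy, value),
                             settings)
    a <- res[res$strategy == comparison[1], ]
    b <- res[res$strategy == comparison[2], ]
    (a$cost - b$cost) / (a$qaly - b$qaly)
  }
  lo <- icer_for(entry$lower)
  hi <- icer_for(entry$upper)
  data.frame(id = id, strategy = strategy,
             icer_lower = lo, icer_upper = hi,
             width = abs(hi - lo), stringsAsFactors = FALSE)
}

#' Full one-way (tornado) analysis
#'
#' Applies [one_way()] to every non-degenerate parameter and returns the
#' entries sorted by descending bar width.
#'
#' @inheritParams one_way
#' @param ids Optional data frame with columns `id`, `strategy` restricting
#'   the parameters varied; default all entries with `upper > lower`.
#' @return Data frame of class `tornado`: one row per parameter, sorted by
#'   descending `width`, with the baseline ICER as attribute
#'   `baseline_icer`.
#' @export
tornado_analysis <- function(params, comparison = c("BCT", "MAST"),
                             settings = econ_settings(), ids = NULL) {
  if (is.null(ids)) {
    keep <- params$upper > params$lower
    ids <- data.frame(id = params$id[keep], strategy = params$strategy[keep],
                      stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(ids)), function(i) {
    one_way(params, ids$id[i], ids$strategy[i], comparison, settings)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$id), , drop = FALSE]
  rownames(out) <- NULL
  base <- strategy_outcomes(params, settings)
  a <- base[base$strategy == comparison[1], ]
  b <- base[base$strategy == comparison[2], ]
  attr(out, "baseline_icer") <- (a$cost - b$cost) / (a$qaly - b$qaly)
  attr(out, "comparison") <- comparison
  class(out) <- c("tornado", "data.frame")
  out
}

#' Build a sampling function for one parameter
#'
#' Moment-matched samplers for probabilistic sensitivity analysis: beta for
#' utilities and transition probabilities, lognormal for costs, both
#' matched to mean = baseline and (natural-scale) standard deviation =
#' (upper - lower) / (2 * 1.96), treating the printed range as a central
#' 95% interval. A degenerate range yields a point mass; a beta whose
#' implied shape parameters are non-positive (baseline at or outside the
#' open unit interval, or a too-wide range) falls back to a point mass with
#' a warning. `constant`-family entries always return the baseline.
#'
#' @param entry One-row parameter entry (see [param_entry()]).
#' @return A function `f(n)` drawing `n` values.
#' @export
fit_distribution <- function(entry) {
  b <- entry$baseline
  s <- (entry$upper - entry$lower) / (2 * 1.96)
  point_mass <- function(n) rep(b, n)
  attr(point_mass, "family") <- "constant"
  attr(point_mass, "pars") <- c(value = b)
  if (entry$family == "constant" || s == 0) return(point_mass)
  if (entry$family == "beta") {
    if (b <= 0 || b >= 1) {
      warning("beta parameter '", entry$id,
              "' has baseline on the support boundary; using a point mass")
      return(point_mass)
    }
    nu <- b * (1 - b) / s^2 - 1
    alpha <- b * nu
    beta <- (1 - b) * nu
    if (alpha <= 0 || beta <= 0) {
      warning("beta parameter '", entry$id,
              "' has non-positive implied shape; using a point mass")
      return(point_mass)
    }
    f <- function(n) stats::rbeta(n, alpha, beta)
    attr(f, "family") <- "beta"
    attr(f, "pars") <- c(alpha = alpha, beta = beta)
    return(f)
  }
  if (entry$family == "lognormal") {
    if (b <= 0) stop("lognormal parameter '", entry$id, "' must be positive")
    sigma2 <- log(1 + (s / b)^2)
    mu <- log(b) - sigma2 / 2
    f <- function(n) stats::rlnorm(n, mu, sqrt(sigma2))
    attr(f, "family") <- "lognormal"
    attr(f, "pars") <- c(mu = mu, sigma = sqrt(sigma2))
    return(f)
  }
  stop("unknown family: ", entry$family)
}

#' Draw one probabilistic parameter set
#'
#' @param params A validated `param_set`.
#' @param samplers Optional pre-built sampler list (from
#'   [build_samplers()]).
#' @param seed Seed for this draw.
#' @return A `param_set` with baselines replaced by the drawn values.
#' @export
draw_param_set <- function(params, samplers = NULL, seed = 1) {
  if (is.null(samplers)) samplers <- build_samplers(params)
  set.seed(seed)
  drawn <- vapply(samplers, function(f) f(1), numeric(1))
  params$baseline <- drawn
  params$lower <- pmin(params$lower, drawn)
  params$upper <- pmax(params$upper, drawn)
  params
}

#' @rdname draw_param_set
#' @return `build_samplers()`: a list of sampler functions, one per
#'   parameter row of `params`.
#' @export
build_samplers <- function(params) {
  lapply(seq_len(nrow(params)), function(i)
    fit_distribution(params[i, , drop = FALSE]))
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo simulation over the parameter distributions: each iteration
#' draws every distribution-family parameter independently (the discount
#' rate, a `constant` entry, stays fixed), reruns the three-strategy model,
#' and records costs and QALYs. The preferred strategy at each
#' willingness-to-pay value is the one with the highest net monetary
#' benefit. Iteration `i` uses its own sub-seed, so any single iteration
#' can be replayed with [draw_param_set()].
#'
#' @param params A validated `param_set`.
#' @param settings An `econ_settings`.
#' @param n_iter Number of iterations (>= 1).
#' @param seed Master seed.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curves
#'   (USD/QALY); the settings' own threshold is always included.
#' @return List of class `psa_result`: `draws` (data frame: iteration,
#'   per-strategy cost and qaly), `ceac` (data frame: wtp, one probability
#'   column per strategy), `selection` (named selection frequencies at the
#'   settings' threshold), `iter_seeds`.
#' @export
run_psa <- function(params, settings = econ_settings(), n_iter = 1000,
                    seed = 1, wtp_grid = seq(0, 60000, by = 2500)) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  wtp_grid <- sort(unique(c(wtp_grid, settings$wtp)))
  samplers <- build_samplers(params)
  set.seed(sub_seed(seed, 101))
  iter_seeds <- sample.int(2147483646L, n_iter)
  ns <- length(strategies())
  cost_mat <- qaly_mat <- matrix(NA_real_, n_iter, ns,
                                 dimnames = list(NULL, strategies()))
  for (i in seq_len(n_iter)) {
    ps_i <- draw_param_set(params, samplers, iter_seeds[i])
    res <- strategy_outcomes(ps_i, settings)
    cost_mat[i, res$strategy] <- res$cost
    qaly_mat[i, res$strategy] <- res$qaly
  }
  # acceptability: share of iterations in which each strategy maximises NMB
  ceac <- t(vapply(wtp_grid, function(w) {
    nmb <- w * qaly_mat - cost_mat
    best <- max.col(nmb, ties.method = "first")
    tabulate(best, ns) / n_iter
  }, numeric(ns)))
  ceac <- data.frame(wtp = wtp_grid, ceac)
  names(ceac)[-1] <- strategies()
  sel <- unlist(ceac[ceac$wtp == settings$wtp, -1])
  draws <- data.frame(iteration = seq_len(n_iter),
                      cost = cost_mat, qaly = qaly_mat)
  structure(list(draws = draws, ceac = ceac, selection = sel,
                 iter_seeds = iter_seeds, n_iter = n_iter),
            class = "psa_result")
}
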
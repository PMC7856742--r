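## Propensity-score estimation, greedy 1:1 nearest-neighbour matching with
## the smallest (reconstruction) group as reference, and balance
## diagnostics.

#' Estimate treatment propensities
#'
#' Fits a multinomial logistic model of strategy on covariates and returns
#' the fitted per-strategy probabilities plus pairwise linearised scores
#' (log-odds) used as matching distances.
#'
#' @param patients A `PatientTable` with a `strategy` column.
#' @param covariates Character vector of covariate columns; defaults to the
#'   full generated covariate dictionary.
#' @return List of class `propensity_scores`: `probs` (n x 3 matrix of
#'   fitted probabilities), `patients`, `covariates`, and the fitted model.
#' @export
estimate_propensity <- function(patients, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(.cohort_covariates, names(patients))
  }
  miss <- setdiff(covariates, names(patients))
  if (length(miss)) stop("covariates absent from table: ",
                         paste(miss, collapse = ", "))
  present <- unique(patients$strategy)
  if (length(present) < 2) {
    stop("propensity model needs at least two strategies; found ",
         length(present))
  }
  dat <- patients[, c("strategy", covariates), drop = FALSE]
  for (cc in covariates) {
    v <- dat[[cc]]
    if (length(unique(v)) < 2) {
      stop("covariate '", cc, "' is constant; drop it before fitting")
    }
    if (is.character(v)) dat[[cc]] <- factor(v)
  }
  dat$strategy <- factor(dat$strategy,
                         levels = intersect(strategies(), present))
  fit <- nnet::multinom(strategy ~ ., data = dat, trace = FALSE,
                        maxit = 500, MaxNWts = 5000)
  probs <- stats::fitted(fit)
  if (length(present) == 2) {           # binomial case: fitted() is a vector
    probs <- cbind(1 - probs, probs)
  }
  colnames(probs) <- levels(dat$strategy)
  # perfect separation: a whole group predicted with certainty
  for (s in levels(dat$strategy)) {
    if (mean(probs[dat$strategy == s, s]) > 1 - 1e-6) {
      stop("group '", s, "' is perfectly predicted by the covariates: ",
           "perfect separation")
    }
  }
  structure(list(probs = probs, patients = patients,
                 covariates = covariates, fit = fit),
            class = "propensity_scores")
}

#' Greedy 1:1 nearest-neighbour matching
#'
#' For each comparison group, matches every reference patient to its nearest
#' unused comparison patient on the pairwise linearised propensity (the
#' log-odds of reference versus that comparison group), without replacement.
#' Reference patients are processed in descending score order; distance ties
#' are broken toward the lowest patient id, so matching is deterministic.
#'
#' @param scores A `propensity_scores` object.
#' @param reference Reference strategy (default the reconstruction group,
#'   the smallest).
#' @param caliper Optional maximum allowed absolute log-odds distance; a
#'   reference patient with no comparison patient inside the caliper raises
#'   an error (the default, `NULL`, imposes none).
#' @return List of class `matched_set`: `pairs` (data frame of reference id
#'   and matched id per comparison group), `matched` (the matched
#'   `PatientTable`), `reference`.
#' @export
match_nearest <- function(scores, reference = "MAST_RECON", caliper = NULL) {
  stopifnot(inherits(scores, "propensity_scores"))
  reference <- match.arg(reference, strategies())
  pat <- scores$patients
  probs <- scores$probs
  if (!reference %in% colnames(probs)) stop("reference group is empty")
  ref_idx <- which(pat$strategy == reference)
  if (length(ref_idx) == 0) stop("reference group is empty")
  comparisons <- setdiff(colnames(probs), reference)
  pairs <- list()
  keep_rows <- ref_idx
  for (g in comparisons) {
    comp_idx <- which(pat$strategy == g)
    if (length(comp_idx) < length(ref_idx)) {
      stop("comparison group ", g, " smaller than reference by ",
           length(ref_idx) - length(comp_idx), " patients")
    }
    # pairwise linearised propensity: log-odds of reference vs this group
    # (probabilities floored away from 0 so quasi-separated rare covariate
    # patterns keep a finite, extreme score)
    lp <- log(pmax(probs[, reference], 1e-12)) -
      log(pmax(probs[, g], 1e-12))
    ref_ord <- ref_idx[order(-lp[ref_idx], pat$patient_id[ref_idx])]
    avail <- comp_idx
    match_for <- integer(length(ref_ord))
    for (k in seq_along(ref_ord)) {
      d <- abs(lp[avail] - lp[ref_ord[k]])
      best <- which(d == min(d))
      if (length(best) > 1) {
        best <- best[which.min(pat$patient_id[avail[best]])]
      }
      if (!is.null(caliper) && d[best] > caliper) {
        stop("no match within caliper for reference patient ",
             pat$patient_id[ref_ord[k]])
      }
      match_for[k] <- avail[best]
      avail <- avail[-best]
    }
    pairs[[g]] <- data.frame(
      reference_id = pat$patient_id[ref_ord],
      matched_id = pat$patient_id[match_for],
      group = g,
      distance = abs(lp[match_for] - lp[ref_ord]),
      stringsAsFactors = FALSE
    )
    keep_rows <- c(keep_rows, match_for)
  }
  matched <- pat[sort(unique(keep_rows)), , drop = FALSE]
  class(matched) <- c("patient_table", "data.frame")
  structure(list(pairs = do.call(rbind, pairs), matched = matched,
                 reference = reference),
            class = "matched_set")
}

pairwise_smd <- function(x1, x2) {
  if (is.numeric(x1)) {
    s2 <- (stats::var(x1) + stats::var(x2)) / 2
    if (s2 == 0) return(0)
    abs(mean(x1) - mean(x2)) / sqrt(s2)
  } else {
    lev <- union(unique(x1), unique(x2))
    smds <- vapply(lev, function(l) {
      p1 <- mean(x1 == l); p2 <- mean(x2 == l)
      s2 <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
      if (s2 == 0) 0 else abs(p1 - p2) / sqrt(s2)
    }, numeric(1))
    max(smds)
  }
}

max_group_smd <- function(x, g) {
  groups <- unique(g)
  if (length(groups) < 2) return(0)
  cmb <- utils::combn(groups, 2)
  max(apply(cmb, 2, function(pair) {
    pairwise_smd(x[g == pair[1]], x[g == pair[2]])
  }))
}

covariate_p_value <- function(x, g) {
  if (is.numeric(x)) {
    stats::anova(stats::aov(x ~ factor(g)))[["Pr(>F)"]][1]
  } else if (attr(x, "ordered_cov") %||% FALSE) {
    stats::kruskal.test(attr(x, "ranks"), factor(g))$p.value
  } else {
    suppressWarnings(stats::chisq.test(table(x, g))$p.value)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.ordered_levels <- list(
  tnm_stage = c("0", "I", "II"),
  bmi_category = c("underweight", "normal", "overweight")
)

#' Covariate balance diagnostics before and after matching
#'
#' Per covariate: the maximum pairwise standardized mean difference (SMD)
#' across the three groups, and a group-difference p-value — one-way ANOVA
#' for continuous covariates, a rank-based Kruskal-Wallis test for ordered
#' categories (TNM stage, BMI class), and a chi-square contingency test for
#' unordered categories — each computed on the pre-matching table and on the
#' matched set.
#'
#' @param pre The full (pre-matching) `PatientTable`.
#' @param post A `matched_set` from [match_nearest()], or a matched
#'   `PatientTable`.
#' @param covariates Covariate columns; default the shared dictionary.
#' @return Data frame of class `balance_report`: `covariate`, `smd_pre`,
#'   `smd_post`, `p_pre`, `p_post`.
#' @export
balance_table <- function(pre, post, covariates = NULL) {
  if (inherits(post, "matched_set")) post <- post$matched
  if (is.null(covariates)) {
    covariates <- intersect(.cohort_covariates, names(pre))
  }
  miss <- setdiff(covariates, intersect(names(pre), names(post)))
  if (length(miss)) stop("covariate(s) absent from a table: ",
                         paste(miss, collapse = ", "))
  one <- function(tab, cc) {
    x <- tab[[cc]]
    if (cc %in% names(.ordered_levels)) {
      r <- as.integer(factor(x, levels = .ordered_levels[[cc]]))
      attr(x, "ordered_cov") <- TRUE
      attr(x, "ranks") <- r
    }
    c(smd = max_group_smd(tab[[cc]], tab$strategy),
      p = covariate_p_value(x, tab$strategy))
  }
  rows <- lapply(covariates, function(cc) {
    a <- one(pre, cc); b <- one(post, cc)
    data.frame(covariate = cc, smd_pre = a[["smd"]], smd_post = b[["smd"]],
               p_pre = a[["p"]], p_post = b[["p"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("balance_report", "data.frame")
  out
}
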
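## Competing-risks estimation: Aalen-Johansen cumulative incidence (via the
## multi-state Kaplan-Meier machinery in `survival`), a permutation Gray
## test for group differences (statistic from `cmprsk`), and conversion of
## cumulative incidences to the annual transition probabilities the Markov
## model consumes.

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Estimates the cumulative incidence function (CIF) for the event of
#' interest and its competing event. Status coding follows the `cmprsk`
#' convention: 0 = censored, 1 = event of interest, 2 = competing event.
#' With no competing events present the cause-1 CIF reduces to
#' 1 - Kaplan-Meier.
#'
#' @param time Event or censoring times (months, positive).
#' @param status Integer status per subject (0/1/2).
#' @param group Optional group labels; the CIF is estimated per group.
#' @return Data frame of class `cif_curve`: `group`, `event_type`
#'   (`"event"`/`"competing"`), `time`, `estimate`, `std_err`, `at_risk` —
#'   a right-continuous step function evaluated at the observed times.
#' @export
cumulative_incidence <- function(time, status, group = NULL) {
  if (length(time) < 1) stop("at least one subject required")
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and non-negative")
  }
  if (!all(status %in% 0:2)) stop("status must be coded 0/1/2")
  if (is.null(group)) group <- rep("all", length(time))
  pieces <- lapply(unique(group), function(g) {
    idx <- group == g
    if (all(status[idx] == 0)) {
      # every subject censored: flat zero curve for both event types
      tt <- sort(unique(time[idx]))
      at_risk <- vapply(tt, function(u) sum(time[idx] >= u), numeric(1))
      return(data.frame(group = g,
                        event_type = rep(c("event", "competing"),
                                         each = length(tt)),
                        time = rep(tt, 2), estimate = 0, std_err = 0,
                        at_risk = rep(at_risk, 2),
                        stringsAsFactors = FALSE))
    }
    st <- factor(status[idx], levels = 0:2,
                 labels = c("censor", "event", "competing"))
    fit <- survival::survfit(survival::Surv(time[idx], st) ~ 1)
    states <- fit$states
    keep <- match(c("event", "competing"), states)
    do.call(rbind, lapply(c(event = 1, competing = 2), function(k) {
      col <- keep[k]
      data.frame(group = g,
                 event_type = c("event", "competing")[k],
                 time = fit$time,
                 estimate = fit$pstate[, col],
                 std_err = fit$std.err[, col],
                 at_risk = fit$n.risk[, 1],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("cif_curve", "data.frame")
  out
}

gray_statistic <- function(time, status, group, event = 1) {
  fit <- cmprsk::cuminc(ftime = time, fstatus = status, group = group,
                        cencode = 0)
  tst <- fit$Tests
  if (is.null(tst) || !as.character(event) %in% rownames(tst)) {
    return(NA_real_)
  }
  tst[as.character(event), "stat"]
}

# Enumerate all distinct assignments of the multiset of group labels.
enumerate_assignments <- function(labels) {
  n <- length(labels)
  uniq <- sort(unique(labels))
  rec <- function(free, counts) {
    if (length(free) == 0) return(matrix(character(0), nrow = 1)[, 0, drop = FALSE])
    lev <- names(counts)[counts > 0]
    out <- list()
    for (l in lev) {
      counts2 <- counts
      counts2[l] <- counts2[l] - 1
      sub <- rec(free[-1], counts2)
      out[[length(out) + 1]] <- cbind(rep(l, nrow(sub)), sub)
    }
    do.call(rbind, out)
  }
  counts <- table(factor(labels, levels = uniq))
  rec(seq_len(n), counts)
}

#' Gray's test with a permutation p-value
#'
#' K-sample comparison of cumulative incidence functions for the event of
#' interest. The test statistic is Gray's K-sample statistic (an integrated
#' weighted difference of subdistribution hazard estimates); the p-value is
#' obtained by permuting group labels rather than from the asymptotic
#' chi-square reference. When the number of distinct label arrangements is
#' no larger than `n_perm`, the exact permutation distribution is
#' enumerated; otherwise `n_perm` random shuffles are used.
#'
#' @param time,status As in [cumulative_incidence()].
#' @param group Group labels; at least two distinct groups.
#' @param event Event code tested (default 1).
#' @param n_perm Number of random permutations (default 2000).
#' @param seed Seed for the permutation stream.
#' @return List of class `gray_test`: `statistic`, `p_value`, `n_perm`,
#'   `exact` (logical).
#' @export
gray_test <- function(time, status, group, event = 1, n_perm = 2000,
                      seed = 1) {
  group <- as.character(group)
  counts <- table(group)
  if (length(counts) < 2) stop("at least two groups required")
  obs <- gray_statistic(time, status, group, event)
  if (is.na(obs)) stop("event of interest absent from the data")
  n_exact <- exp(lgamma(length(group) + 1) - sum(lgamma(counts + 1)))
  if (n_exact <= n_perm + 0.5) {
    perms <- enumerate_assignments(group)
    stats <- apply(perms, 1, function(g)
      gray_statistic(time, status, g, event))
    p <- mean(stats >= obs - 1e-12)
    res <- list(statistic = obs, p_value = p, n_perm = nrow(perms),
                exact = TRUE)
  } else {
    set.seed(seed)
    stats <- replicate(n_perm,
      gray_statistic(time, status, sample(group), event))
    p <- (1 + sum(stats >= obs - 1e-12)) / (1 + n_perm)
    res <- list(statistic = obs, p_value = p, n_perm = n_perm, exact = FALSE)
  }
  class(res) <- "gray_test"
  res
}

#' Convert a cumulative incidence to a per-cycle transition probability
#'
#' Converts a cumulative incidence `P1` observed over `t1` years to the
#' probability over a cycle of `t2` years, through the constant
#' instantaneous rate `r = -ln(1 - P1) / t1` and `P = 1 - exp(-r * t2)`.
#' With `t1 == t2` the conversion is the identity.
#'
#' @param p1 Cumulative incidence over the follow-up span, in `[0, 1)`.
#' @param t1 Follow-up span in years.
#' @param t2 Target cycle length in years (default 1).
#' @return Transition probability per cycle of length `t2`.
#' @export
annual_probability <- function(p1, t1, t2 = 1) {
  if (any(p1 < 0 | p1 >= 1)) stop("p1 must be in [0, 1)")
  stopifnot(t1 > 0, t2 > 0)
  -expm1(log1p(-p1) / t1 * t2)
}

#' @rdname annual_probability
#' @param p Probability over a period of `t` years.
#' @param t Period length in years.
#' @return `prob_to_rate()`: the instantaneous rate per year;
#'   `rate_to_prob()`: the probability over `t` years.
#' @export
prob_to_rate <- function(p, t = 1) {
  if (any(p < 0 | p >= 1)) stop("p must be in [0, 1)")
  -log1p(-p) / t
}

#' @rdname annual_probability
#' @param r Instantaneous rate per year (non-negative).
#' @export
rate_to_prob <- function(r, t = 1) {
  if (any(r < 0)) stop("rate must be non-negative")
  -expm1(-r * t)
}

#' Per-transition event histories from a patient table
#'
#' Builds the four event histories the model needs, with the clock reset at
#' state entry (the cohort model is memoryless): disease-free to local
#' recurrence (metastasis as the competing first transition), disease-free
#' to distant metastasis (recurrence competing), recurrence to metastasis
#' on the sub-cohort with an observed recurrence, and metastasis to death
#' on the sub-cohort with observed metastasis.
#'
#' @param patients A `PatientTable` with simulated or recorded event columns
#'   (`t_lr`, `t_met`, `t_death`, event flags, `censor_time`).
#' @return Named list (`dfs_lr`, `dfs_met`, `lr_met`, `met_death`) of data
#'   frames with columns `time` (months), `status` (0/1/2), `group`.
#' @export
transition_histories <- function(patients) {
  need <- c("t_lr", "t_met", "t_death", "event_lr", "event_met",
            "event_death", "censor_time", "strategy")
  miss <- setdiff(need, names(patients))
  if (length(miss)) stop("patient table lacks event columns: ",
                         paste(miss, collapse = ", "))
  p <- patients
  lr_first <- p$event_lr
  met_first <- p$event_met & !p$event_lr
  t_first <- ifelse(lr_first, p$t_lr,
                    ifelse(met_first, p$t_met, p$censor_time))
  dfs_lr <- data.frame(time = t_first,
                       status = ifelse(lr_first, 1L, ifelse(met_first, 2L, 0L)),
                       group = p$strategy, stringsAsFactors = FALSE)
  dfs_met <- data.frame(time = t_first,
                        status = ifelse(met_first, 1L, ifelse(lr_first, 2L, 0L)),
                        group = p$strategy, stringsAsFactors = FALSE)
  sub_lr <- p[p$event_lr, , drop = FALSE]
  lr_met <- data.frame(
    time = ifelse(sub_lr$event_met, sub_lr$t_met - sub_lr$t_lr,
                  sub_lr$censor_time - sub_lr$t_lr),
    status = ifelse(sub_lr$event_met, 1L, 0L),
    group = sub_lr$strategy, stringsAsFactors = FALSE)
  sub_met <- p[p$event_met, , drop = FALSE]
  met_death <- data.frame(
    time = ifelse(sub_met$event_death, sub_met$t_death - sub_met$t_met,
                  sub_met$censor_time - sub_met$t_met),
    status = ifelse(sub_met$event_death, 1L, 0L),
    group = sub_met$strategy, stringsAsFactors = FALSE)
  # guard against zero durations from near-immediate transitions
  lr_met$time <- pmax(lr_met$time, 1e-6)
  met_death$time <- pmax(met_death$time, 1e-6)
  list(dfs_lr = dfs_lr, dfs_met = dfs_met, lr_met = lr_met,
       met_death = met_death)
}

#' Derive annual transition probabilities from CIF curves
#'
#' Reads, for each strategy and transition, the terminal cumulative
#' incidence of the event of interest and the follow-up span of the curve,
#' and converts them to an annual probability with [annual_probability()].
#' Estimates are clamped to `[0, 1]`.
#'
#' @param curves Named list (`dfs_lr`, `dfs_met`, `lr_met`, `met_death`) of
#'   `cif_curve` data frames (see [cumulative_incidence()]), one per
#'   transition, each carrying the three strategy groups.
#' @param horizons Optional named numeric vector (months) overriding the
#'   follow-up span read from each curve.
#' @return A `transition_set` data frame (as [transition_set()]), with an
#'   attribute `details`: per strategy/transition, the terminal CIF, its
#'   standard error, the span used, and the delta-method standard error of
#'   the annual probability.
#' @export
derive_transition_set <- function(curves, horizons = NULL) {
  slots <- c(dfs_lr = "p_dfs_to_lr", dfs_met = "p_dfs_to_met",
             lr_met = "p_lr_to_met", met_death = "p_met_to_death")
  miss <- setdiff(names(slots), names(curves))
  if (length(miss)) stop("missing curve(s): ", paste(miss, collapse = ", "))
  out <- data.frame(strategy = strategies(), stringsAsFactors = FALSE)
  details <- list()
  for (tr in names(slots)) {
    cv <- curves[[tr]]
    if (is.null(cv) || nrow(cv) == 0) stop("empty curve for ", tr)
    vals <- ses <- numeric(length(strategies()))
    for (i in seq_along(strategies())) {
      s <- strategies()[i]
      sub <- cv[cv$group == s & cv$event_type == "event", , drop = FALSE]
      if (nrow(sub) == 0) { vals[i] <- 0; ses[i] <- NA_real_; next }
      last <- sub[which.max(sub$time), ]
      span_months <- if (!is.null(horizons) && tr %in% names(horizons)) {
        horizons[[tr]]
      } else max(sub$time)
      t1 <- span_months / 12
      p1 <- min(max(last$estimate, 0), 1 - 1e-12)
      p_ann <- min(max(annual_probability(p1, t1), 0), 1)
      r <- prob_to_rate(p1, t1)
      se <- exp(-r) * last$std_err / ((1 - p1) * t1)
      vals[i] <- p_ann; ses[i] <- se
      details[[paste(tr, s, sep = ".")]] <- data.frame(
        transition = slots[[tr]], strategy = s, terminal_cif = last$estimate,
        se_cif = last$std_err, span_months = span_months,
        p_annual = p_ann, se_annual = se, stringsAsFactors = FALSE)
    }
    out[[slots[[tr]]]] <- vals
  }
  class(out) <- c("transition_set", "data.frame")
  attr(out, "details") <- do.call(rbind, c(details, make.row.names = FALSE))
  out
}

#' Estimate a transition set from patient-level data
#'
#' Convenience wrapper: builds the per-transition event histories, estimates
#' per-strategy CIF curves, and converts terminal incidences to annual
#' probabilities.
#'
#' @param patients A `PatientTable` with event history columns.
#' @return A `transition_set` (see [derive_transition_set()]); the CIF
#'   curves are attached as attribute `curves`.
#' @export
estimate_transitions <- function(patients) {
  hist <- transition_histories(patients)
  curves <- lapply(hist, function(h) {
    if (nrow(h) == 0) return(structure(h, class = c("cif_curve", class(h))))
    cumulative_incidence(h$time, h$status, h$group)
  })
  empty <- vapply(curves, function(cv) nrow(cv) == 0, logical(1))
  if (any(empty)) {
    # keep placeholder rows so derive_transition_set can report zeros
    for (nm in names(curves)[empty]) {
      curves[[nm]] <- data.frame(group = NA_character_, event_type = "event",
                                 time = 0, estimate = 0, std_err = 0,
                                 at_risk = 0, stringsAsFactors = FALSE)
    }
  }
  ts <- derive_transition_set(curves)
  attr(ts, "curves") <- curves
  ts
}
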
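#' @keywords internal
"_PACKAGE"

#' Surgical strategy labels
#'
#' The three compared strategies: mastectomy (`MAST`), mastectomy with
#' reconstruction (`MAST_RECON`) and breast-conserving therapy (`BCT`).
#' Every per-strategy map in the package is total over these three labels.
#'
#' @return Character vector of the three strategy identifiers.
#' @export
strategies <- function() c("MAST", "MAST_RECON", "BCT")

## Parameter ids that must be present in a valid ParamSet.
## Per-strategy ids are required once per strategy; shared ids once with an
## empty strategy field.
.shared_param_ids <- c(
  "cost_lr_hospital_y1", "cost_lr_outpatient_y1",
  "cost_met_hospital", "cost_met_outpatient",
  "cost_predeath_hospital", "cost_predeath_outpatient",
  "utility_lr_y1", "utility_metastasis",
  "discount_rate"
)

.per_strategy_param_ids <- c(
  "cost_hospital_y1", "cost_outpatient_y1", "cost_followup_annual",
  "cost_transport_y1", "cost_lost_work_y1",
  "utility_dfs_y1", "utility_dfs_plus",
  "p_dfs_to_lr", "p_dfs_to_met", "p_lr_to_met", "p_met_to_death"
)

.param_families <- c("beta", "lognormal", "constant")

#' Economic evaluation settings
#'
#' Container for the decision-model settings: discount rate, horizon,
#' willingness-to-pay threshold, currency conversion and the indirect-cost
#' inputs. Costs are kept in USD throughout; CNY enters only at the
#' transportation boundary via `fx_rate`.
#'
#' @param discount_rate Annual discount rate applied to both costs and
#'   QALYs (fraction per year).
#' @param n_cycles Number of model cycles (years) to run.
#' @param cycle_length_months Cycle length in months (the model is annual).
#' @param wtp Willingness-to-pay threshold in USD per QALY (3x per-capita
#'   GDP).
#' @param fx_rate Exchange rate, CNY per USD.
#' @param fare_per_visit Transportation cost per hospital visit, in CNY.
#' @param annual_wage Average annual wage in USD, used for lost-work costs.
#' @param half_cycle_correction Logical; accrue state rewards on the average
#'   of start- and end-of-cycle occupancy.
#'
#' @return A list of class `econ_settings`.
#' @export
econ_settings <- function(discount_rate = 0.03,
                          n_cycles = 60L,
                          cycle_length_months = 12,
                          wtp = 27931.04,
                          fx_rate = 6.93,
                          fare_per_visit = 80,
                          annual_wage = 9338.67,
                          half_cycle_correction = TRUE) {
  stopifnot(discount_rate >= 0, n_cycles >= 1, wtp > 0,
            fx_rate > 0, cycle_length_months > 0)
  structure(
    list(discount_rate = discount_rate,
         n_cycles = as.integer(n_cycles),
         cycle_length_months = cycle_length_months,
         wtp = wtp,
         fx_rate = fx_rate,
         fare_per_visit = fare_per_visit,
         annual_wage = annual_wage,
         half_cycle_correction = isTRUE(half_cycle_correction)),
    class = "econ_settings"
  )
}

#' Load economic settings from a YAML file
#'
#' @param path Path to a YAML file; defaults to the packaged settings.
#' @param overrides Optional named list overriding individual settings.
#' @return An `econ_settings` object.
#' @export
load_settings <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "econ_settings.yaml", package = "ebccea")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(overrides)) raw[names(overrides)] <- overrides
  do.call(econ_settings, raw)
}

#' Load and validate the model parameter set
#'
#' Reads the packaged machine-readable input table (state costs in USD,
#' health utilities, annual transition probabilities, with per-parameter
#' ranges and distribution families) or a user-supplied CSV with the same
#' columns. Parameters are keyed by `id` plus, for per-strategy entries, a
#' `strategy` column. Rows with missing bounds get a +/-20% range around the
#' baseline, clamped to the family's support.
#'
#' @param path CSV path; `NULL` uses the packaged table.
#' @param overrides Optional named list of baseline replacements. Names are
#'   either a shared id (`"utility_metastasis"`) or `"id:STRATEGY"` for
#'   per-strategy entries (`"p_dfs_to_met:BCT"`). Applied before validation;
#'   the range of an overridden entry is refilled as +/-20% around the new
#'   baseline.
#'
#' @return A data frame of class `param_set` with columns `id`, `strategy`,
#'   `baseline`, `lower`, `upper`, `family`, `units`, `label`.
#' @export
load_parameters <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_parameters.csv", package = "ebccea")
  }
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ps <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed_cols <- c("id", "strategy", "baseline", "lower", "upper", "family")
  miss <- setdiff(needed_cols, names(ps))
  if (length(miss)) stop("parameter file lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"units" %in% names(ps)) ps$units <- NA_character_
  if (!"label" %in% names(ps)) ps$label <- ps$id
  ps$strategy[is.na(ps$strategy)] <- ""

  if (!is.null(overrides)) {
    for (key in names(overrides)) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      id <- parts[1]
      strat <- if (length(parts) > 1) parts[2] else ""
      row <- which(ps$id == id & ps$strategy == strat)
      if (length(row) != 1) stop("override names unknown parameter: ", key)
      ps$baseline[row] <- overrides[[key]]
      ps$lower[row] <- NA_real_
      ps$upper[row] <- NA_real_
    }
  }

  # +/-20% fill for absent ranges, clamped to the family's support
  fill <- is.na(ps$lower) | is.na(ps$upper)
  if (any(fill)) {
    lo <- 0.8 * ps$baseline[fill]
    hi <- 1.2 * ps$baseline[fill]
    beta_row <- ps$family[fill] == "beta"
    lo[beta_row] <- pmax(lo[beta_row], 0)
    hi[beta_row] <- pmin(hi[beta_row], 1)
    lo <- pmax(lo, 0)
    ps$lower[fill] <- pmin(lo, hi)
    ps$upper[fill] <- pmax(lo, hi)
  }

  validate_param_set(ps)
}

validate_param_set <- function(ps) {
  key <- paste(ps$id, ps$strategy, sep = ":")
  dup <- key[duplicated(key)]
  if (length(dup)) stop("duplicated parameter id(s): ",
                        paste(dup, collapse = ", "))
  required <- c(paste0(.shared_param_ids, ":"),
                as.vector(outer(.per_strategy_param_ids, strategies(),
                                paste, sep = ":")))
  miss <- setdiff(required, key)
  if (length(miss)) {
    stop("missing required parameter(s): ",
         paste(sub(":$", "", miss), collapse = ", "))
  }
  bad <- !(ps$family %in% .param_families)
  if (any(bad)) stop("unknown distribution family for: ",
                     paste(ps$id[bad], collapse = ", "))
  for (i in seq_len(nrow(ps))) {
    nm <- sub(":$", "", key[i])
    b <- ps$baseline[i]; lo <- ps$lower[i]; hi <- ps$upper[i]
    if (any(is.na(c(b, lo, hi)))) stop("non-numeric values for parameter ", nm)
    if (!(lo <= b && b <= hi)) {
      stop("parameter ", nm, " violates lower <= baseline <= upper")
    }
    if (ps$family[i] == "beta" && (lo < 0 || hi > 1)) {
      stop("beta-family parameter ", nm, " outside [0, 1]")
    }
    if (ps$family[i] == "lognormal" && b <= 0) {
      stop("lognormal-family parameter ", nm, " must be positive")
    }
  }
  class(ps) <- c("param_set", "data.frame")
  ps
}

#' Look up a single parameter entry
#'
#' @param params A `param_set`.
#' @param id Parameter id.
#' @param strategy Strategy label for per-strategy entries; `""` (default)
#'   for shared entries.
#' @return One-row data frame for the entry.
#' @export
param_entry <- function(params, id, strategy = "") {
  row <- which(params$id == id & params$strategy == strategy)
  if (length(row) != 1) {
    stop("no such parameter: ", id,
         if (nzchar(strategy)) paste0(" [", strategy, "]") else "")
  }
  params[row, , drop = FALSE]
}

#' @rdname param_entry
#' @return `param_value()`: the baseline value as a scalar.
#' @export
param_value <- function(params, id, strategy = "") {
  param_entry(params, id, strategy)$baseline
}

#' Transportation cost for a course of hospital visits
#'
#' Number of inpatient plus outpatient visits times the per-visit fare
#' (taxi-based, in CNY), converted to USD.
#'
#' @param n_visits Number of visits (non-negative).
#' @param fare_cny Fare per visit in CNY.
#' @param fx CNY per USD exchange rate.
#' @return Cost in USD.
#' @export
transportation_cost <- function(n_visits, fare_cny = 80, fx = 6.93) {
  if (any(n_visits < 0)) stop("n_visits must be non-negative")
  stopifnot(fare_cny > 0, fx > 0)
  n_visits * fare_cny / fx
}

#' Daily wage implied by an annual wage
#'
#' @param annual_wage Annual wage in USD.
#' @return USD per day (annual wage / 365).
#' @export
daily_wage <- function(annual_wage = 9338.67) {
  stopifnot(annual_wage > 0)
  annual_wage / 365
}

#' Productivity (lost-work) cost
#'
#' Days lost to hospitalisation and outpatient visits in the first treatment
#' year, valued at the average daily wage.
#'
#' @param days Days of lost work (non-negative).
#' @param annual_wage Annual wage in USD.
#' @return Cost in USD.
#' @export
lost_work_cost <- function(days, annual_wage = 9338.67) {
  if (any(days < 0)) stop("days must be non-negative")
  days * daily_wage(annual_wage)
}

#' Assemble the per-state cost schedule
#'
#' Attaches the cost parameters to model states and transitions. For each
#' strategy the first disease-free year carries surgery-year hospital and
#' outpatient costs plus transportation and lost-work costs; subsequent
#' disease-free years carry the annual follow-up cost; the first year of
#' local recurrence carries the recurrence hospital and outpatient costs;
#' each metastatic year carries the annual metastasis costs; and the
#' three-months-before-death costs are a one-time reward on the transition
#' into death.
#'
#' @param params A validated `param_set`.
#' @param lr_plus One of `"followup"` (default) or `"lr_y1"`: cost attached
#'   to local-recurrence years beyond the first, for which the input table
#'   has no dedicated entry. The default reverts to the strategy's annual
#'   follow-up cost.
#' @return A list of class `cost_schedule`: per strategy, the per-cycle
#'   costs `dfs_y1`, `dfs_plus`, `lr_y1`, `lr_plus`, `met`, and the one-time
#'   `death_transition` cost.
#' @export
assemble_cost_schedule <- function(params, lr_plus = c("followup", "lr_y1")) {
  lr_plus <- match.arg(lr_plus)
  v <- function(id, s = "") param_value(params, id, s)
  lr_entry <- v("cost_lr_hospital_y1") + v("cost_lr_outpatient_y1")
  met <- v("cost_met_hospital") + v("cost_met_outpatient")
  death <- v("cost_predeath_hospital") + v("cost_predeath_outpatient")
  out <- lapply(strategies(), function(s) {
    dfs_y1 <- v("cost_hospital_y1", s) + v("cost_outpatient_y1", s) +
      v("cost_transport_y1", s) + v("cost_lost_work_y1", s)
    followup <- v("cost_followup_annual", s)
    list(dfs_y1 = dfs_y1,
         dfs_plus = followup,
         lr_y1 = lr_entry,
         lr_plus = if (lr_plus == "followup") followup else lr_entry,
         met = met,
         death_transition = death)
  })
  names(out) <- strategies()
  structure(out, class = "cost_schedule")
}

#' Assemble the per-state utility set
#'
#' @param params A validated `param_set`.
#' @param lr_plus One of `"dfs_plus"` (default) or `"lr_y1"`: utility used
#'   for local-recurrence years beyond the first (no dedicated entry in the
#'   input table; the default reverts to the strategy's subsequent-year
#'   disease-free utility).
#' @return A list of class `utility_set`: per strategy, utilities `dfs_y1`,
#'   `dfs_plus`, `lr_y1`, `lr_plus`, `met`, `death` (death fixed at 0).
#' @export
utility_set <- function(params, lr_plus = c("dfs_plus", "lr_y1")) {
  lr_plus <- match.arg(lr_plus)
  v <- function(id, s = "") param_value(params, id, s)
  out <- lapply(strategies(), function(s) {
    dfs_plus <- v("utility_dfs_plus", s)
    u <- list(dfs_y1 = v("utility_dfs_y1", s),
              dfs_plus = dfs_plus,
              lr_y1 = v("utility_lr_y1"),
              lr_plus = if (lr_plus == "dfs_plus") dfs_plus else v("utility_lr_y1"),
              met = v("utility_metastasis"),
              death = 0)
    bad <- unlist(u) < 0 | unlist(u) > 1
    if (any(bad)) stop("utilities outside [0, 1] for strategy ", s)
    u
  })
  names(out) <- strategies()
  structure(out, class = "utility_set")
}

#' Extract the annual transition probabilities
#'
#' @param params A validated `param_set`.
#' @return Data frame of class `transition_set`, one row per strategy with
#'   columns `p_dfs_to_lr`, `p_dfs_to_met`, `p_lr_to_met`, `p_met_to_death`.
#' @export
transition_set <- function(params) {
  cols <- c("p_dfs_to_lr", "p_dfs_to_met", "p_lr_to_met", "p_met_to_death")
  out <- data.frame(strategy = strategies(), stringsAsFactors = FALSE)
  for (cc in cols) {
    out[[cc]] <- vapply(strategies(), function(s) param_value(params, cc, s),
                        numeric(1))
  }
  for (i in seq_len(nrow(out))) {
    exit_dfs <- out$p_dfs_to_lr[i] + out$p_dfs_to_met[i]
    if (exit_dfs > 1) stop("DFS exit probabilities exceed 1 for ",
                           out$strategy[i])
  }
  class(out) <- c("transition_set", "data.frame")
  out
}
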
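## Synthetic patient-level cohort generator.
##
## No patient-level data ship with the package; this module generates
## synthetic registry-like tables with the statistical structure the
## downstream stages assume: covariate marginals matching the published
## post-matching cohort, optional covariate-dependent treatment assignment
## (to create confounding for the matching stage to remove), and
## competing-risks exponential event histories consistent with the annual
## transition probabilities of the decision model.

# Derive a reproducible sub-stream seed from a master seed (kept < 2^31).
sub_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483647
}

.table1_counts <- list(
  MAST_RECON = list(
    age = c(mean = 38.63, sd = 6.94),
    insurance = c(provincial = 13, city = 102, other = 90),
    lesion_location = c(left = 110, right = 95, double = 0),
    histology = c(dcis = 10, invasive_ductal = 158, invasive_lobular = 5,
                  other = 32),
    tnm_stage = c(`0` = 4, I = 6, II = 195),
    bmi_category = c(underweight = 21, normal = 144, overweight = 40),
    hormone_receptor = c(positive = 105, negative = 19, mixed = 73,
                         unknown = 8),
    patient_source = c(city = 126, province = 71, other = 8),
    neoadjuvant_chemo = c(no = 165, yes = 40),
    targeted_therapy = c(no = 167, yes = 38)
  ),
  BCT = list(
    age = c(mean = 38.60, sd = 7.58),
    insurance = c(provincial = 12, city = 100, other = 93),
    lesion_location = c(left = 112, right = 93, double = 0),
    histology = c(dcis = 5, invasive_ductal = 168, invasive_lobular = 3,
                  other = 29),
    tnm_stage = c(`0` = 3, I = 5, II = 197),
    bmi_category = c(underweight = 15, normal = 164, overweight = 26),
    hormone_receptor = c(positive = 106, negative = 17, mixed = 75,
                         unknown = 7),
    patient_source = c(city = 129, province = 65, other = 11),
    neoadjuvant_chemo = c(no = 169, yes = 36),
    targeted_therapy = c(no = 172, yes = 33)
  ),
  MAST = list(
    age = c(mean = 39.03, sd = 7.21),
    insurance = c(provincial = 11, city = 119, other = 75),
    lesion_location = c(left = 109, right = 95, double = 1),
    histology = c(dcis = 6, invasive_ductal = 164, invasive_lobular = 2,
                  other = 33),
    tnm_stage = c(`0` = 7, I = 6, II = 192),
    bmi_category = c(underweight = 15, normal = 148, overweight = 42),
    # published counts for this row are inconsistent with the group size;
    # the printed percentages (which sum to 100) are used instead
    hormone_receptor = c(positive = 66.10, negative = 7.12, mixed = 24.75,
                         unknown = 2.03),
    patient_source = c(city = 131, province = 66, other = 8),
    neoadjuvant_chemo = c(no = 169, yes = 36),
    targeted_therapy = c(no = 171, yes = 34)
  )
)

.cohort_covariates <- c("age", "insurance", "lesion_location", "histology",
                        "tnm_stage", "bmi_category", "hormone_receptor",
                        "patient_source", "neoadjuvant_chemo",
                        "targeted_therapy")

.ordered_covariates <- c("tnm_stage", "bmi_category")

#' Covariate specification for the cohort generator
#'
#' Marginal covariate distributions mirroring the published post-matching
#' cohort: age as a truncated normal and nine categorical covariates
#' (insurance, lesion location, histology, TNM stage, BMI category, hormone
#' receptor status, patient source, neoadjuvant chemotherapy, targeted
#' therapy) as probability vectors.
#'
#' @param strategy `NULL` for the pooled (all-groups) spec, or one of
#'   [strategies()] for that group's column.
#' @return A list of class `covariate_spec`: `age = c(mean, sd)` plus one
#'   named probability vector per categorical covariate.
#' @export
default_covariate_spec <- function(strategy = NULL) {
  src <- if (is.null(strategy)) {
    pooled <- .table1_counts[[1]]
    for (nm in names(pooled)[-1]) {
      p <- rowMeans(vapply(.table1_counts,
                           function(g) g[[nm]] / sum(g[[nm]]),
                           numeric(length(pooled[[nm]]))))
      pooled[[nm]] <- p
    }
    pooled$age <- c(mean = mean(vapply(.table1_counts,
                                       function(g) g$age[["mean"]],
                                       numeric(1))),
                    sd = mean(vapply(.table1_counts,
                                     function(g) g$age[["sd"]], numeric(1))))
    pooled
  } else {
    match.arg(strategy, strategies())
    g <- .table1_counts[[strategy]]
    g[-1] <- lapply(g[-1], function(x) x / sum(x))
    g
  }
  validate_covariate_spec(structure(src, class = "covariate_spec"))
}

validate_covariate_spec <- function(spec) {
  if (is.null(spec$age) || spec$age[["sd"]] <= 0) {
    stop("covariate spec: age must have positive sd")
  }
  for (nm in setdiff(names(spec), "age")) {
    p <- spec[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("covariate spec: probabilities for '", nm, "' must sum to 1")
    }
  }
  spec
}

#' Default covariate-dependent treatment-assignment model
#'
#' A multinomial-logit assignment mechanism (reference level `MAST`) used to
#' generate *confounded* synthetic cohorts: younger, normal-BMI, stage 0/I
#' and neoadjuvant-treated patients are more likely to receive
#' breast-conserving therapy or reconstruction, mimicking the selection the
#' real registry exhibits before matching. Intercepts give approximate
#' pre-matching shares of 75% mastectomy, 8% reconstruction, 17%
#' breast-conserving therapy.
#'
#' @return A list of class `assignment_model` with a formula and a
#'   coefficient matrix (rows `MAST_RECON`, `BCT`).
#' @export
default_assignment_model <- function() {
  formula <- ~ I((age - 39) / 7) + bmi_category + neoadjuvant_chemo + tnm_stage
  # columns follow model.matrix on the factor codings below
  coef <- rbind(
    MAST_RECON = c(`(Intercept)` = -2.4, age = -0.6, bmi_normal = 0.4,
                   bmi_overweight = -0.3, nac_yes = 0.4,
                   tnm_I = -0.3, tnm_II = -0.6),
    BCT = c(`(Intercept)` = -1.5, age = -0.5, bmi_normal = 0.5,
            bmi_overweight = -0.4, nac_yes = 0.3,
            tnm_I = -0.2, tnm_II = -0.4)
  )
  structure(list(formula = formula, coef = coef, reference = "MAST"),
            class = "assignment_model")
}

assignment_design <- function(covs) {
  z <- (covs$age - 39) / 7
  cbind(`(Intercept)` = 1,
        age = z,
        bmi_normal = as.numeric(covs$bmi_category == "normal"),
        bmi_overweight = as.numeric(covs$bmi_category == "overweight"),
        nac_yes = as.numeric(covs$neoadjuvant_chemo == "yes"),
        tnm_I = as.numeric(covs$tnm_stage == "I"),
        tnm_II = as.numeric(covs$tnm_stage == "II"))
}

draw_covariates <- function(n, spec) {
  age <- stats::rnorm(n, spec$age[["mean"]], spec$age[["sd"]])
  # resample outside the plausible adult range
  while (any(bad <- age < 18 | age > 90)) {
    age[bad] <- stats::rnorm(sum(bad), spec$age[["mean"]], spec$age[["sd"]])
  }
  out <- data.frame(age = age)
  for (nm in setdiff(.cohort_covariates, "age")) {
    p <- spec[[nm]]
    out[[nm]] <- names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
  }
  out
}

#' Generate a synthetic cohort (covariates and strategy)
#'
#' Two modes. With `n_per_group`, each strategy's patients are drawn from
#' that group's covariate spec (balanced design, as after matching). With an
#' `assignment` model, `n` patients are drawn from the pooled spec and
#' treatment is assigned by a multinomial logit on covariates, producing the
#' confounded pre-matching structure the propensity-score stage removes.
#'
#' @param n Total cohort size (assignment mode). Ignored when `n_per_group`
#'   is given.
#' @param n_per_group Named integer vector over [strategies()].
#' @param spec A `covariate_spec`, or (in `n_per_group` mode) a named list
#'   of specs per strategy; defaults to the published marginals.
#' @param assignment An `assignment_model`, or `NULL`.
#' @param seed Master seed; covariate and assignment draws use separate
#'   sub-streams.
#' @return A `PatientTable` data frame: `patient_id`, covariates, `strategy`.
#' @export
generate_cohort <- function(n = NULL, n_per_group = NULL,
                            spec = NULL, assignment = NULL, seed = 1) {
  if (is.null(n_per_group)) {
    stopifnot(!is.null(n), n >= 0)
    if (is.null(spec)) spec <- default_covariate_spec()
    validate_covariate_spec(spec)
    set.seed(sub_seed(seed, 1))
    covs <- draw_covariates(n, spec)
    if (n == 0) {
      covs$strategy <- character(0)
    } else if (is.null(assignment)) {
      set.seed(sub_seed(seed, 2))
      covs$strategy <- sample(strategies(), n, replace = TRUE)
    } else {
      X <- assignment_design(covs)
      eta <- X %*% t(assignment$coef)
      expeta <- cbind(1, exp(eta))  # reference first
      probs <- expeta / rowSums(expeta)
      labs <- c(assignment$reference, rownames(assignment$coef))
      set.seed(sub_seed(seed, 2))
      covs$strategy <- labs[apply(probs, 1, function(p)
        sample.int(length(p), 1, prob = p))]
    }
  } else {
    stopifnot(all(names(n_per_group) %in% strategies()))
    pieces <- lapply(names(n_per_group), function(s) {
      sp <- if (is.null(spec)) default_covariate_spec(s)
            else if (inherits(spec, "covariate_spec")) spec
            else spec[[s]]
      validate_covariate_spec(sp)
      set.seed(sub_seed(seed, 1 + match(s, strategies())))
      cv <- draw_covariates(n_per_group[[s]], sp)
      cv$strategy <- rep(s, n_per_group[[s]])
      cv
    })
    covs <- do.call(rbind, pieces)
  }
  covs <- cbind(patient_id = seq_len(nrow(covs)), covs)
  rownames(covs) <- NULL
  class(covs) <- c("patient_table", "data.frame")
  covs
}

#' Hazard specification from annual transition probabilities
#'
#' Converts each strategy's annual transition probabilities to constant
#' (exponential) event rates via `r = -ln(1 - p)`; probabilities of 1 are
#' represented by a large capped rate (`-ln(1e-12)` per year, i.e. a
#' near-immediate transition).
#'
#' @param transitions A `transition_set` (see [transition_set()]).
#' @param admin_censor Administrative censoring horizon in months.
#' @return List of class `hazard_spec`: per strategy, annual rates
#'   `lr`, `met`, `lr_met`, `met_death`, plus `admin_censor`.
#' @export
hazard_spec <- function(transitions, admin_censor = 94) {
  stopifnot(admin_censor > 0)
  rate <- function(p) -log1p(-pmin(pmax(p, 0), 1 - 1e-12))
  out <- lapply(seq_len(nrow(transitions)), function(i) {
    list(lr = rate(transitions$p_dfs_to_lr[i]),
         met = rate(transitions$p_dfs_to_met[i]),
         lr_met = rate(transitions$p_lr_to_met[i]),
         met_death = rate(transitions$p_met_to_death[i]))
  })
  names(out) <- transitions$strategy
  structure(list(rates = out, admin_censor = admin_censor),
            class = "hazard_spec")
}

#' Simulate competing-risks event histories
#'
#' Fills a cohort's event history under the natural-history hypothesis of
#' the decision model: from disease-free survival, local recurrence and
#' distant metastasis compete (exponential clocks); after local recurrence a
#' fresh clock runs to metastasis; after metastasis a fresh clock runs to
#' breast-cancer death. Administrative censoring is applied at
#' `admin_censor` months; latent times beyond the censoring horizon are
#' reported as missing.
#'
#' @param patients A `PatientTable` with a `strategy` column.
#' @param hazards A `hazard_spec`.
#' @param seed Seed for the event sub-stream.
#' @return The input table with columns `t_lr`, `t_met`, `t_death` (months,
#'   `NA` when unobserved), logical flags `event_lr`, `event_met`,
#'   `event_death`, and `censor_time`.
#' @export
simulate_events <- function(patients, hazards, seed = 1) {
  stopifnot(inherits(hazards, "hazard_spec"))
  n <- nrow(patients)
  cens <- hazards$admin_censor
  t_lr <- t_met <- t_death <- rep(NA_real_, n)
  lat_lr <- lat_met <- lat_death <- rep(Inf, n)
  set.seed(sub_seed(seed, 11))
  rexp_months <- function(m, r) {
    if (r <= 0) rep(Inf, m) else stats::rexp(m, r) * 12
  }
  for (s in unique(patients$strategy)) {
    idx <- which(patients$strategy == s)
    r <- hazards$rates[[s]]
    if (is.null(r)) stop("no hazards for strategy ", s)
    m <- length(idx)
    e_lr <- rexp_months(m, r$lr)
    e_met0 <- rexp_months(m, r$met)
    lr_first <- e_lr < e_met0
    lat_lr[idx[lr_first]] <- e_lr[lr_first]
    # metastasis time: direct, or after recurrence with a fresh clock
    w_lrmet <- rexp_months(m, r$lr_met)
    met_time <- ifelse(lr_first, e_lr + w_lrmet, e_met0)
    lat_met[idx] <- met_time
    w_death <- rexp_months(m, r$met_death)
    lat_death[idx] <- met_time + w_death
  }
  obs <- function(t) ifelse(is.finite(t) & t <= cens, t, NA_real_)
  t_lr <- obs(lat_lr); t_met <- obs(lat_met); t_death <- obs(lat_death)
  out <- patients
  out$t_lr <- t_lr
  out$t_met <- t_met
  out$t_death <- t_death
  out$event_lr <- !is.na(t_lr)
  out$event_met <- !is.na(t_met)
  out$event_death <- !is.na(t_death)
  out$censor_time <- rep(cens, n)
  out
}

#' Write / read a patient table as CSV
#'
#' @param patients A `PatientTable`.
#' @param path Output CSV path.
#' @return `write_patient_table()` returns `path` invisibly;
#'   `read_patient_table()` returns the `PatientTable`.
#' @export
write_patient_table <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patient_table
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) stop("patient table not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("patient_table", "data.frame")
  out
}
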
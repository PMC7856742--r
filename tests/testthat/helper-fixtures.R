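# Shared fixtures built in code.

# Write a (possibly modified) copy of the packaged parameter table to a
# temporary CSV and return its path.
write_params_csv <- function(modify = identity) {
  src <- system.file("extdata", "table2_parameters.csv", package = "ebccea")
  df <- utils::read.csv(src, stringsAsFactors = FALSE)
  df$strategy[is.na(df$strategy)] <- ""
  df <- modify(df)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# A parameter table whose costs are all zero (constant family, so it stays
# valid) — used for degenerate-schedule checks.
zero_cost_params <- function() {
  path <- write_params_csv(function(df) {
    cost_rows <- grepl("^cost_", df$id)
    df$baseline[cost_rows] <- 0
    df$lower[cost_rows] <- 0
    df$upper[cost_rows] <- 0
    df$family[cost_rows] <- "constant"
    df
  })
  load_parameters(path)
}

# Fabricate a two-group propensity_scores object from prescribed log-odds
# (reference vs comparison), so matching can be exercised directly.
fake_scores <- function(ref_lp, comp_lp,
                        reference = "MAST_RECON", comparison = "MAST") {
  lp <- c(ref_lp, comp_lp)
  p_ref <- exp(lp) / (1 + exp(lp))
  probs <- cbind(p_ref, 1 - p_ref)
  colnames(probs) <- c(reference, comparison)
  patients <- data.frame(
    patient_id = seq_along(lp),
    strategy = rep(c(reference, comparison), c(length(ref_lp), length(comp_lp))),
    stringsAsFactors = FALSE
  )
  structure(list(probs = probs, patients = patients,
                 covariates = character(0), fit = NULL),
            class = "propensity_scores")
}

# Brute-force minimal-total-distance 1:1 assignment between two score sets.
brute_force_assignment <- function(ref, comp) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_total <- Inf
  for (p in perms(seq_along(comp))) {
    total <- sum(abs(ref - comp[p]))
    if (total < best_total) { best_total <- total; best <- p }
  }
  list(assignment = best, total = best_total)
}

# A confounded synthetic cohort shared by the PSM tests.
confounded_cohort <- function(n = 2600, seed = 402) {
  generate_cohort(n = n, assignment = default_assignment_model(), seed = seed)
}
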
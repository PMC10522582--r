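# Shared fixture builders. All randomness takes an explicit seed so tests
# are reproducible and independent of execution order.

# balanced annotation: n_per_cell patients in every response x arm cell,
# each with a pre and a post sample
balanced_annotation <- function(responses = c("PD", "SD", "PR", "CR"),
                                n_per_cell = 3) {
  grid <- expand.grid(response = responses, arm = c("placebo", "ATRA"),
                      idx = seq_len(n_per_cell), stringsAsFactors = FALSE)
  grid$patient_id <- sprintf("p%03d", seq_len(nrow(grid)))
  ann <- do.call(rbind, lapply(c("pre", "post"), function(tm) {
    data.frame(sample_id = paste0(grid$patient_id, "_", tm),
               patient_id = grid$patient_id, arm = grid$arm, time = tm,
               response = grid$response, stringsAsFactors = FALSE)
  }))
  as_sample_annotation(ann)
}

# draw y from the random-intercept model at given cell means
simulate_lmm_y <- function(design, cell_mean, patient_sd = 0.5,
                           residual_sd = 0.5) {
  dat <- design$data
  mu <- mapply(cell_mean, as.character(dat$response),
               as.character(dat$arm), as.character(dat$time))
  pid <- design$patient
  b <- stats::rnorm(length(unique(pid)), 0, patient_sd)
  names(b) <- unique(pid)
  mu + b[pid] + stats::rnorm(length(mu), 0, residual_sd)
}

# balanced cohort (no NE) used for operating-characteristic simulations:
# every design cell is occupied, which the Table 2 frequencies do not
# guarantee at moderate n (the placebo arm had a single CR)
balanced_cohort <- function(n_per_arm = 60L, seed = 1L) {
  probs <- c(CR = 0.25, PR = 0.25, SD = 0.25, PD = 0.25, NE = 0)
  generate_cohort(cohort_config(
    n_per_arm = c(ATRA = n_per_arm, placebo = n_per_arm),
    response_probs = list(ATRA = probs, placebo = probs),
    censor_prob = 0, seed = seed))
}

# hand-built contrast_results row, for exercising the decision rules
# without fitting anything
result_row <- function(protein, family, label = "x", response_hi = NA,
                       response_lo = NA, response = NA, arm = NA,
                       estimate = 0, p_raw = 1, p_adj = 1) {
  data.frame(protein = protein, family = family, label = label,
             response_hi = response_hi, response_lo = response_lo,
             response = response, arm = arm, estimate = estimate,
             se = 0.1, z = estimate / 0.1, p_raw = p_raw, p_adj = p_adj,
             degenerate = FALSE, converged = TRUE, boundary = FALSE,
             stringsAsFactors = FALSE)
}

# a tiny raw protein_matrix with controllable missingness
toy_matrix <- function(values, proteins = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- proteins %||% sprintf("prot%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  protein_matrix(m, state = "raw_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
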
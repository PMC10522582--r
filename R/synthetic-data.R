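#' Configuration for a synthetic two-arm trial cohort
#'
#' Defaults reproduce the published trial's stated world: 53 vs 55
#' patients, the observed per-arm response frequencies, median OS 16.2 vs
#' 10.7 months and median PFS 7.1 vs 4.2 months (treatment arm first in
#' each pair is `ATRA`), and a 10% independent censoring probability
#' mirroring the loss-to-follow-up assumption of the design.
#'
#' @param n_per_arm Integer pair `c(ATRA, placebo)`.
#' @param response_probs Named list with elements `ATRA` and `placebo`,
#'   each a probability vector over `CR, PR, SD, PD, NE` summing to 1.
#' @param median_os_months,median_pfs_months Named numeric pairs
#'   (`ATRA`, `placebo`) of exponential survival medians, in months.
#' @param censor_prob Probability that a patient's OS (and PFS) time is
#'   independently right-censored.
#' @param seed Integer seed driving all sampling.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_arm = c(ATRA = 53L, placebo = 55L),
                          response_probs = list(
                            ATRA = c(CR = 4, PR = 9, SD = 14, PD = 19, NE = 7) / 53,
                            placebo = c(CR = 1, PR = 4, SD = 12, PD = 31, NE = 7) / 55),
                          median_os_months = c(ATRA = 16.2, placebo = 10.7),
                          median_pfs_months = c(ATRA = 7.1, placebo = 4.2),
                          censor_prob = 0.10, seed = 1L) {
  stopifnot(length(n_per_arm) == 2, all(n_per_arm >= 1))
  cats <- c("CR", "PR", "SD", "PD", "NE")
  for (a in c("ATRA", "placebo")) {
    p <- response_probs[[a]]
    if (is.null(p) || !all(cats %in% names(p))) {
      stop("response_probs$", a, " must be named over CR, PR, SD, PD, NE")
    }
    p <- p[cats]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("response_probs$", a, " must be non-negative and sum to 1 (tol 1e-12)")
    }
    response_probs[[a]] <- p
  }
  stopifnot(all(median_os_months > 0), all(median_pfs_months > 0),
            censor_prob >= 0, censor_prob < 1)
  nm <- names(n_per_arm)
  if (is.null(nm)) nm <- c("ATRA", "placebo")
  if (!setequal(nm, ARM_LEVELS)) stop("n_per_arm must be named ATRA, placebo")
  structure(list(n_per_arm = stats::setNames(as.integer(n_per_arm), nm),
                 response_probs = response_probs,
                 median_os_months = median_os_months,
                 median_pfs_months = median_pfs_months,
                 censor_prob = censor_prob, seed = as.integer(seed)),
            class = "cohort_config")
}

# all (intra, extra) lesion pairs whose composite equals `overall`
lesion_pairs_for <- function(overall) {
  grid <- expand.grid(intra = LESION_LEVELS, extra = LESION_LEVELS,
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$intra == "NONE" & grid$extra == "NONE"), ]
  grid[combine_lesion_responses(grid$intra, grid$extra) == overall, ]
}

#' Generate a synthetic trial cohort
#'
#' Samples per-patient arm membership, an overall response drawn from the
#' arm's category frequencies, a lesion-level (intrahepatic,
#' extrahepatic) pair drawn uniformly from the preimage of that overall
#' response under [combine_lesion_responses], and exponential OS/PFS times
#' at the configured medians. PFS is capped at OS, so the marginal median
#' of observed PFS is `1 / (1/median_pfs + 1/median_os)` rather than the
#' configured latent value. Each patient has one independent exponential
#' follow-up limit whose rate is calibrated so the probability of being
#' censored before death equals `censor_prob`; both endpoints share it.
#'
#' @param config A [cohort_config].
#' @return A data frame of class `trial_cohort`: `patient_id`, `arm`,
#'   `intra_resp`, `extra_resp`, `response`, `os_months`, `os_event`,
#'   `pfs_months`, `pfs_event`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  arms <- rep(names(config$n_per_arm), config$n_per_arm)
  n <- length(arms)
  cats <- c("CR", "PR", "SD", "PD", "NE")
  response <- character(n)
  intra <- character(n); extra <- character(n)
  for (i in seq_len(n)) {
    p <- config$response_probs[[arms[i]]]
    response[i] <- sample(cats, 1, prob = p)
    pairs <- lesion_pairs_for(response[i])
    j <- sample.int(nrow(pairs), 1)
    intra[i] <- pairs$intra[j]; extra[i] <- pairs$extra[j]
  }
  rate_os <- log(2) / config$median_os_months[arms]
  rate_pfs <- log(2) / config$median_pfs_months[arms]
  os <- stats::rexp(n, rate_os)
  pfs <- pmin(stats::rexp(n, rate_pfs), os)  # progression cannot follow death
  # one independent exponential follow-up limit per patient, with its rate
  # calibrated so that P(censored before death) equals censor_prob;
  # dependent censoring (e.g. at a fraction of the event time) would bias
  # the product-limit estimator
  cp <- config$censor_prob
  fup <- if (cp == 0) rep(Inf, n) else stats::rexp(n, rate_os * cp / (1 - cp))
  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    arm = factor(arms, levels = ARM_LEVELS),
    intra_resp = intra, extra_resp = extra,
    response = factor(response, levels = RESPONSE_LEVELS),
    os_months = pmin(os, fup),
    os_event = as.integer(os <= fup),
    pfs_months = pmin(pfs, fup),
    pfs_event = as.integer(pfs <= fup),
    stringsAsFactors = FALSE
  )
  class(out) <- c("trial_cohort", "data.frame")
  out
}

#' Configuration for a synthetic paired pre/post proteome
#'
#' The generator emulates a label-free spectral-count experiment: each
#' protein has a log2-scale baseline abundance, each patient a random
#' intercept, each sample Gaussian residual noise; marker archetypes add a
#' log2 shift restricted to one arm, one response group, and one time
#' point. Relative abundances are scaled to a per-sample library size and
#' rounded to counts, then cells are knocked out as missing.
#'
#' @param n_proteins Number of proteins.
#' @param n_spiked_per_archetype Spiked proteins for each of the four
#'   archetypes `pre_CR_up`, `pre_PR_up`, `post_CR_up`,
#'   `post_responder_down` (`4 * n_spiked_per_archetype <= n_proteins`).
#' @param effect_size Archetype shift on the log2-abundance scale.
#' @param patient_sd,residual_sd Standard deviations (log2 scale) of the
#'   patient random intercept and the per-sample residual.
#' @param dropout_prob Per-cell missingness. Under `dropout_mode =
#'   "uniform"` this is a constant Bernoulli rate; under `"intensity"` the
#'   rate follows a logistic curve in log-abundance (low-abundance
#'   proteins drop out more) with `dropout_prob` as the average rate
#'   anchor.
#' @param dropout_mode `"uniform"` (default) or `"intensity"`.
#' @param library_size_range Pair of positive totals; each sample's total
#'   spectral count is drawn uniformly from this range.
#' @param spike_arm Arm carrying the archetype effects (default `ATRA`).
#' @param n_patients Optional subset of consenting patients contributing
#'   proteomes; `NULL` means the whole cohort.
#' @param seed Integer seed.
#' @return A validated list of class `proteome_config`.
#' @export
proteome_config <- function(n_proteins = 300L, n_spiked_per_archetype = 5L,
                            effect_size = 2.0, patient_sd = 0.5,
                            residual_sd = 0.5, dropout_prob = 0.10,
                            dropout_mode = c("uniform", "intensity"),
                            library_size_range = c(5e4, 1.5e5),
                            spike_arm = "ATRA", n_patients = NULL,
                            seed = 1L) {
  dropout_mode <- match.arg(dropout_mode)
  stopifnot(n_proteins >= 1, n_spiked_per_archetype >= 0,
            patient_sd > 0, residual_sd > 0,
            dropout_prob >= 0, dropout_prob <= 1,
            length(library_size_range) == 2, all(library_size_range > 0),
            library_size_range[1] <= library_size_range[2],
            spike_arm %in% ARM_LEVELS)
  if (4L * n_spiked_per_archetype > n_proteins) {
    stop("4 * n_spiked_per_archetype exceeds n_proteins")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_spiked_per_archetype = as.integer(n_spiked_per_archetype),
                 effect_size = effect_size, patient_sd = patient_sd,
                 residual_sd = residual_sd, dropout_prob = dropout_prob,
                 dropout_mode = dropout_mode,
                 library_size_range = library_size_range,
                 spike_arm = spike_arm, n_patients = n_patients,
                 seed = as.integer(seed)),
            class = "proteome_config")
}

ARCHETYPES <- c("pre_CR_up", "pre_PR_up", "post_CR_up", "post_responder_down")

# which samples of the annotation an archetype touches, given the spiked arm
archetype_mask <- function(archetype, annotation, arm) {
  in_arm <- annotation$arm == arm
  switch(archetype,
    pre_CR_up = in_arm & annotation$time == "pre" & annotation$response == "CR",
    pre_PR_up = in_arm & annotation$time == "pre" & annotation$response == "PR",
    post_CR_up = in_arm & annotation$time == "post" & annotation$response == "CR",
    post_responder_down = in_arm & annotation$time == "post" &
      annotation$response %in% c("CR", "PR"),
    stop("unknown archetype: ", archetype))
}

archetype_sign <- function(archetype) {
  ifelse(archetype == "post_responder_down", -1, 1)
}

#' Generate a paired pre/post proteome for a cohort
#'
#' Every (subset) patient contributes a pre-treatment and a post-treatment
#' sample. Log2 abundances are
#' `baseline_p + patient_intercept + archetype_shift + residual`; samples
#' are scaled so the total expected count equals a drawn library size and
#' rounded; dropout then masks cells as missing (`NA`).
#'
#' @param cohort A `trial_cohort` from [generate_cohort].
#' @param config A [proteome_config].
#' @return List with `matrix` (a raw-count [protein_matrix]), `annotation`
#'   (a `sample_annotation`), and `truth` (data frame `protein`,
#'   `archetype`, `arm` listing every spiked protein).
#' @export
generate_proteome <- function(cohort, config = proteome_config()) {
  stopifnot(inherits(cohort, "trial_cohort"), nrow(cohort) >= 1)
  set.seed(config$seed)
  pats <- cohort
  if (!is.null(config$n_patients)) {
    stopifnot(config$n_patients >= 1, config$n_patients <= nrow(cohort))
    pats <- cohort[sort(sample.int(nrow(cohort), config$n_patients)), ]
  }
  np <- nrow(pats)
  ann <- data.frame(
    sample_id = paste0(rep(pats$patient_id, each = 2), "_",
                       rep(TIME_LEVELS, np)),
    patient_id = rep(pats$patient_id, each = 2),
    arm = rep(as.character(pats$arm), each = 2),
    time = rep(TIME_LEVELS, np),
    response = rep(as.character(pats$response), each = 2),
    stringsAsFactors = FALSE
  )
  ann <- as_sample_annotation(ann)
  P <- config$n_proteins
  proteins <- sprintf("PROT%04d", seq_len(P))
  k <- config$n_spiked_per_archetype
  truth <- data.frame(protein = character(0), archetype = character(0),
                      arm = character(0), stringsAsFactors = FALSE)
  if (k > 0 && config$effect_size != 0) {  # zero effect means nothing is spiked
    truth <- data.frame(protein = proteins[seq_len(4 * k)],
                        archetype = rep(ARCHETYPES, each = k),
                        arm = config$spike_arm, stringsAsFactors = FALSE)
  }
  S <- nrow(ann)
  baseline <- stats::rnorm(P, mean = 5, sd = 2)        # log2 scale
  if (nrow(truth) > 0) {
    # archetype proteins are mid-abundance: a differential marker that
    # dominates the library (the lognormal tail puts single proteins near
    # 20% of total spectra) would, once spiked, depress every other
    # protein in the affected samples through the total-count
    # normalization and masquerade as hundreds of false interactions
    baseline[seq_len(nrow(truth))] <- stats::rnorm(nrow(truth), 5, 1)
  }
  # patient intercepts are protein-specific: a shared shift would scale the
  # whole sample and vanish under total-count normalization
  pat_int <- matrix(stats::rnorm(P * np, 0, config$patient_sd), P, np,
                    dimnames = list(NULL, pats$patient_id))
  logab <- matrix(baseline, P, S) + pat_int[, ann$patient_id] +
    matrix(stats::rnorm(P * S, 0, config$residual_sd), P, S)
  for (i in seq_len(nrow(truth))) {
    mask <- archetype_mask(truth$archetype[i], ann, truth$arm[i])
    logab[i, mask] <- logab[i, mask] +
      archetype_sign(truth$archetype[i]) * config$effect_size
  }
  rel <- 2^logab
  lib <- stats::runif(S, config$library_size_range[1],
                      config$library_size_range[2])
  counts <- round(sweep(rel, 2, colSums(rel) / lib, "/"))
  dimnames(counts) <- list(proteins, ann$sample_id)
  drop_p <- if (config$dropout_mode == "uniform") {
    matrix(config$dropout_prob, P, S)
  } else {
    # logistic in log-abundance with midpoint at the dropout_prob quantile,
    # so low-abundance proteins drop out more and the overall rate stays
    # near the configured value
    q <- stats::quantile(logab, probs = config$dropout_prob, names = FALSE)
    stats::plogis(-(logab - q) * 1.5)
  }
  dropped <- matrix(stats::runif(P * S) < drop_p, P, S)
  counts[dropped] <- NA_real_
  list(matrix = protein_matrix(counts, state = "raw_counts"),
       annotation = ann, truth = truth)
}

#' Write the synthetic artifacts as plain text
#'
#' @param proteome Output of [generate_proteome].
#' @param cohort The `trial_cohort` used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: `matrix.tsv`, `annotation.csv`,
#'   `cohort.csv`, `truth.csv`.
#' @export
write_synthetic_dataset <- function(proteome, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             annotation = file.path(dir, "annotation.csv"),
             cohort = file.path(dir, "cohort.csv"),
             truth = file.path(dir, "truth.csv"))
  write_protein_matrix(proteome$matrix, paths["matrix"])
  utils::write.csv(proteome$annotation, paths["annotation"], row.names = FALSE)
  utils::write.csv(cohort, paths["cohort"], row.names = FALSE)
  utils::write.csv(proteome$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
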
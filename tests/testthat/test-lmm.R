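test_that("build_design produces the expected dummy-coded columns", {
  # 2 responses x 2 arms x 2 times, main effects: intercept + 1 + 1 + 1
  ann2 <- balanced_annotation(responses = c("PD", "CR"), n_per_cell = 2)
  d2 <- build_design(ann2, interactions = "none")
  expect_equal(ncol(d2$X), 4)
  # 4 responses: intercept + 3 response + arm + time
  ann4 <- balanced_annotation(n_per_cell = 2)
  d4 <- build_design(ann4, interactions = "none")
  expect_equal(ncol(d4$X), 6)
  # adding the arm x response interaction: 3 extra columns
  d4i <- build_design(ann4, interactions = "arm_response")
  expect_equal(ncol(d4i$X), 9)
  # independently constructed indicator matrix for the main-effects part
  ind <- cbind(1,
               ann4$response == "SD", ann4$response == "PR",
               ann4$response == "CR",
               ann4$arm == "ATRA", ann4$time == "post")
  storage.mode(ind) <- "double"
  expect_equal(unname(d4$X), unname(ind), ignore_attr = TRUE)
  # and for the interaction columns
  ind_int <- ind[, 2:4] * ind[, 5]
  expect_equal(unname(d4i$X[, 7:9]), unname(ind_int), ignore_attr = TRUE)
})

test_that("build_design rejects single-level factors and bad references", {
  ann <- balanced_annotation(responses = c("PD", "CR"), n_per_cell = 2)
  one_arm <- ann[ann$arm == "ATRA", ]
  class(one_arm) <- class(ann)
  expect_error(build_design(one_arm), "arm")
  expect_error(build_design(ann, reference_levels = c(response = "SD",
                                                      arm = "placebo",
                                                      time = "pre")),
               "absent")
})

test_that("NE samples are excluded before fitting", {
  ann <- balanced_annotation(n_per_cell = 2)
  extra <- data.frame(sample_id = c("ne1_pre", "ne1_post"),
                      patient_id = "ne1", arm = "ATRA",
                      time = c("pre", "post"), response = "NE")
  ann_ne <- as_sample_annotation(rbind(as.data.frame(ann), extra))
  d <- build_design(ann_ne)
  expect_false(any(grepl("NE", colnames(d$X))))
  expect_equal(nrow(d$X), nrow(ann))
})

test_that("constant response gives an exact zero-variance fit", {
  ann <- balanced_annotation(n_per_cell = 2)
  d <- build_design(ann, interactions = "none")
  fit <- fit_protein_lmm(rep(3.25, nrow(d$X)), d, protein = "const")
  expect_true(fit$converged)
  expect_equal(unname(fit$beta["(Intercept)"]), 3.25)
  expect_equal(unname(fit$beta[-1]), rep(0, length(fit$beta) - 1))
  expect_equal(fit$var_patient, 0)
  expect_equal(fit$var_resid, 0)
})

test_that("with one observation per patient the fit collapses to OLS", {
  # closed-form OLS oracle: with no replication within patient the
  # random intercept and residual are only identified through their sum,
  # the implied covariance is proportional to the identity, and the GLS
  # estimate equals ordinary least squares
  grid <- expand.grid(response = c("PD", "SD", "PR", "CR"),
                      arm = c("placebo", "ATRA"), time = c("pre", "post"),
                      idx = 1:4, stringsAsFactors = FALSE)
  ann <- as_sample_annotation(data.frame(
    sample_id = sprintf("s%03d", seq_len(nrow(grid))),
    patient_id = sprintf("q%03d", seq_len(nrow(grid))),  # all distinct
    arm = grid$arm, time = grid$time, response = grid$response))
  d <- build_design(ann, interactions = "none")
  set.seed(31)
  y <- stats::rnorm(nrow(d$X), 5, 1)
  fit <- fit_protein_lmm(y, d)
  expect_true(fit$converged)
  X <- d$X
  beta_ols <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_equal(unname(fit$beta), unname(beta_ols), tolerance = 1e-6)
  # covariance matches the OLS covariance with the REML residual total
  s2 <- sum((y - X %*% beta_ols)^2) / (length(y) - ncol(X))
  expect_equal(unname(fit$vcov), unname(s2 * solve(crossprod(X))),
               tolerance = 1e-4)
})

test_that("rank deficiency after missing-data dropout is recorded, not raised", {
  ann <- balanced_annotation(n_per_cell = 3)
  d <- build_design(ann, interactions = "none")
  set.seed(32)
  y <- stats::rnorm(nrow(d$X))
  y[ann$time == "post"] <- NA       # time column becomes constant
  fit <- fit_protein_lmm(y, d)
  expect_false(fit$converged)
  expect_match(fit$message, "rank")
  # and test_contrast degrades to NA rather than erroring
  row <- test_contrast(fit, rep(0, ncol(d$X)))
  expect_true(is.na(row$p_raw))
})

test_that("simulation recovery: fixed effects are unbiased", {
  # simulate from the model itself; mean absolute bias of beta-hat stays
  # below 0.05 over replicates (criterion uses 200 patients, 200 reps;
  # run at 96 patients x 150 reps to stay inside the time budget --
  # bias, unlike variance, does not grow as n shrinks)
  ann <- balanced_annotation(n_per_cell = 12)  # 96 patients
  d <- build_design(ann, interactions = "none")
  beta_true <- c(5, 0.8, -0.5, 1.2, 0.3, -0.7)
  mu <- drop(d$X %*% beta_true)
  set.seed(77)
  nrep <- 150
  est <- matrix(NA_real_, nrep, length(beta_true))
  for (r in seq_len(nrep)) {
    b <- stats::rnorm(length(unique(d$patient)), 0, 0.5)
    names(b) <- unique(d$patient)
    y <- mu + b[d$patient] + stats::rnorm(nrow(d$X), 0, 0.5)
    fit <- fit_protein_lmm(y, d)
    est[r, ] <- fit$beta
  }
  bias <- colMeans(est) - beta_true
  expect_lt(mean(abs(bias)), 0.05)
})

test_that("variance components are recovered on average", {
  ann <- balanced_annotation(n_per_cell = 10)
  d <- build_design(ann, interactions = "none")
  set.seed(41)
  vps <- vrs <- numeric(40)
  for (r in seq_len(40)) {
    b <- stats::rnorm(length(unique(d$patient)), 0, 0.6)
    names(b) <- unique(d$patient)
    y <- 3 + b[d$patient] + stats::rnorm(nrow(d$X), 0, 0.4)
    fit <- fit_protein_lmm(y, d)
    vps[r] <- fit$var_patient; vrs[r] <- fit$var_resid
  }
  expect_lt(abs(mean(vps) - 0.36), 0.06)
  expect_lt(abs(mean(vrs) - 0.16), 0.03)
})

test_that("test_contrast implements the Wald z machinery", {
  # crafted fit with known covariance: matrix arithmetic oracle
  S <- matrix(c(0.04, 0.01, 0.00,
                0.01, 0.09, 0.02,
                0.00, 0.02, 0.16), 3, 3)
  fit <- structure(list(protein = "p", beta = c(a = 1, b = 2.5, c = -1),
                        vcov = S, var_patient = 0.1, var_resid = 0.2,
                        n_obs = 50, converged = TRUE, boundary = FALSE,
                        message = ""), class = "lmm_fit")
  # zero contrast
  r0 <- test_contrast(fit, c(0, 0, 0))
  expect_equal(r0$estimate, 0); expect_equal(r0$p_raw, 1)
  # identity contrast matches the coefficient's own Wald test
  r1 <- test_contrast(fit, c(0, 1, 0))
  expect_equal(r1$estimate, 2.5)
  expect_equal(r1$se, sqrt(0.09))
  expect_equal(r1$p_raw, 2 * pnorm(-abs(2.5 / 0.3)))
  # z^2 equals the Wald chi-square
  expect_equal(r1$z^2, (2.5 / 0.3)^2)
  # difference contrast: SE = sqrt(S22 + S33 - 2 S23)
  r2 <- test_contrast(fit, c(0, 1, -1))
  expect_equal(r2$se, sqrt(0.09 + 0.16 - 2 * 0.02))
  expect_equal(r2$estimate, 3.5)
  # degenerate SEs
  fit$vcov <- matrix(0, 3, 3)
  rd <- test_contrast(fit, c(0, 1, 0))
  expect_equal(rd$p_raw, 0); expect_true(rd$degenerate)
  rz <- test_contrast(fit, c(0, 0, 0))
  expect_equal(rz$p_raw, 1); expect_false(rz$degenerate)
  expect_error(test_contrast(fit, c(1, 0)), "length")
})

test_that("enumerate_contrasts emits the four families with correct counts", {
  ann <- balanced_annotation(n_per_cell = 2)
  d <- build_design(ann, interactions = "full")
  ctr <- enumerate_contrasts(d)
  tab <- table(ctr$info$family)
  expect_equal(as.integer(tab[c("pairwise_pre", "interaction_arm_response",
                                "pre_post_within", "interaction_arm_time")]),
               c(12L, 6L, 8L, 4L))
  expect_false(anyDuplicated(ctr$info$label) > 0)
  expect_error(enumerate_contrasts(build_design(ann, interactions = "none")),
               "full")
})

test_that("every contrast reproduces its cell-mean difference", {
  # cell-means oracle: invert the saturated design on arbitrary cell
  # means and check each contrast equals the corresponding difference
  ann <- balanced_annotation(n_per_cell = 2)
  d <- build_design(ann, interactions = "full")
  cells <- expand.grid(response = d$levels$response, arm = d$levels$arm,
                       time = d$levels$time, stringsAsFactors = FALSE)
  set.seed(13)
  mu <- stats::rnorm(nrow(cells), 0, 2)
  cm <- function(r, a, t) mu[cells$response == r & cells$arm == a &
                               cells$time == t]
  Xc <- t(sapply(seq_len(nrow(cells)), function(i)
    protrial:::design_cell_row(d, cells$response[i], cells$arm[i],
                               cells$time[i])))
  beta <- solve(Xc, mu)
  ctr <- enumerate_contrasts(d)
  for (j in seq_len(nrow(ctr$contrasts))) {
    info <- ctr$info[j, ]
    got <- sum(ctr$contrasts[j, ] * beta)
    want <- switch(info$family,
      pairwise_pre = cm(info$response_hi, info$arm, "pre") -
        cm(info$response_lo, info$arm, "pre"),
      interaction_arm_response =
        (cm(info$response_hi, "ATRA", "pre") - cm(info$response_lo, "ATRA", "pre")) -
        (cm(info$response_hi, "placebo", "pre") - cm(info$response_lo, "placebo", "pre")),
      pre_post_within = cm(info$response, info$arm, "post") -
        cm(info$response, info$arm, "pre"),
      interaction_arm_time =
        (cm(info$response, "ATRA", "post") - cm(info$response, "ATRA", "pre")) -
        (cm(info$response, "placebo", "post") - cm(info$response, "placebo", "pre")))
    expect_equal(got, want, tolerance = 1e-10, label = info$label)
  }
})

test_that("adjust_bh is a correct step-up procedure", {
  expect_equal(adjust_bh(0.03), 0.03)                     # single p
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)),      # hand step-up
               c(0.04, 0.04, 0.04, 0.04))
  # hand step-up on an uneven vector:
  # sorted p = (.001,.02,.03,.9); q_i = p_i * 4/i = (.004,.04,.04,.9)
  expect_equal(adjust_bh(c(0.02, 0.9, 0.001, 0.03)),
               c(0.04, 0.9, 0.004, 0.04))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # independent oracle + properties on random vectors
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- adjust_bh(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  # NA passthrough
  expect_equal(adjust_bh(c(0.01, NA, 0.04)),
               c(0.02, NA, 0.04))
})

test_that("fits are invariant to sample-row permutation", {
  ann <- balanced_annotation(n_per_cell = 3)
  d <- build_design(ann, interactions = "full")
  set.seed(55)
  y <- simulate_lmm_y(d, function(r, a, t) 4 + (r == "CR") * 1.5)
  fit <- fit_protein_lmm(y, d)
  perm <- sample(nrow(ann))
  ann_p <- ann[perm, ]; class(ann_p) <- class(ann)
  d_p <- build_design(ann_p, interactions = "full")
  fit_p <- fit_protein_lmm(y[perm], d_p)
  expect_equal(fit$beta, fit_p$beta, tolerance = 1e-6)
  expect_equal(fit$var_patient, fit_p$var_patient, tolerance = 1e-5)
})

test_that("run_contrast_analysis returns a tidy adjusted table", {
  coh <- balanced_cohort(32, seed = 14)  # large enough to occupy all cells
  pr <- generate_proteome(coh, proteome_config(n_proteins = 6,
                                               n_spiked_per_archetype = 0,
                                               dropout_prob = 0, seed = 14))
  m <- normalize_and_log(pr$matrix)
  res <- run_contrast_analysis(m, pr$annotation)
  expect_s3_class(res, "contrast_results")
  expect_equal(nrow(res), 6 * 30)     # 12 + 6 + 8 + 4 contrasts per protein
  expect_true(all(res$p_adj >= res$p_raw - 1e-12, na.rm = TRUE))
  # BH is applied within family: re-adjusting one family reproduces p_adj
  f1 <- res$family == "pairwise_pre"
  expect_equal(res$p_adj[f1], adjust_bh(res$p_raw[f1]))
  # estimates are finite and labelled
  expect_true(all(is.finite(res$estimate)))
  expect_true(all(res$converged))
})
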
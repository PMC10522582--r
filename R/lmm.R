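#' Build the fixed-effect design for the per-protein mixed model
#'
#' Dummy-codes response evaluation, treatment arm, and time point with
#' the stated reference levels (default PD / placebo / pre), optionally
#' augmented with interaction terms, and records the patient grouping
#' vector for the random intercept. Not-evaluable (NE) samples are
#' excluded before coding.
#'
#' @param annotation A `sample_annotation` (see [as_sample_annotation]).
#' @param reference_levels Named character vector with entries `response`,
#'   `arm`, `time`.
#' @param interactions `"none"` (main effects only, the base model),
#'   `"arm_response"`, `"arm_time"`, or `"full"` (all interactions up to
#'   the three-way; a saturated cell-means parameterization, required by
#'   [enumerate_contrasts]).
#' @param drop_ne Exclude NE samples (default TRUE).
#' @return An `lmm_design`: list with the model matrix `X`, `patient`
#'   grouping, the retained `sample_id`s, factor `data`, `formula`, and
#'   `levels`.
#' @export
build_design <- function(annotation,
                         reference_levels = c(response = "PD",
                                              arm = "placebo", time = "pre"),
                         interactions = c("full", "none", "arm_response",
                                          "arm_time"),
                         drop_ne = TRUE) {
  interactions <- match.arg(interactions)
  stopifnot(inherits(annotation, "sample_annotation"))
  ann <- annotation
  if (drop_ne) ann <- ann[ann$response != "NE", , drop = FALSE]
  dat <- data.frame(
    response = droplevels(factor(ann$response)),
    arm = droplevels(factor(ann$arm)),
    time = droplevels(factor(ann$time))
  )
  single <- names(dat)[vapply(dat, nlevels, integer(1)) < 2]
  if (length(single)) {
    stop("factor(s) with a single level after NE exclusion: ",
         paste(single, collapse = ", "))
  }
  for (f in names(dat)) {
    ref <- reference_levels[[f]]
    if (!ref %in% levels(dat[[f]])) {
      stop("reference level ", ref, " absent from factor ", f)
    }
    dat[[f]] <- stats::relevel(dat[[f]], ref)
  }
  formula <- switch(interactions,
    none = ~ response + arm + time,
    arm_response = ~ response * arm + time,
    arm_time = ~ response + arm * time,
    full = ~ response * arm * time)
  X <- stats::model.matrix(formula, dat)
  structure(list(X = X, patient = ann$patient_id,
                 sample_id = ann$sample_id, data = dat, formula = formula,
                 interactions = interactions,
                 levels = lapply(dat, levels)),
            class = "lmm_design")
}

# model-matrix row for one design cell (response, arm, time)
design_cell_row <- function(design, response, arm, time) {
  nd <- data.frame(
    response = factor(response, levels = design$levels$response),
    arm = factor(arm, levels = design$levels$arm),
    time = factor(time, levels = design$levels$time)
  )
  drop(stats::model.matrix(design$formula, nd))
}

#' Fit the per-protein linear mixed model
#'
#' REML fit of `y ~ X + (1 | patient)` via `lme4`, where `X` is the
#' design's fixed-effect matrix. Samples with missing `y` are dropped
#' first. Rank deficiency after dropout, or too few observations or
#' patients, yields a non-converged fit record rather than an error, so a
#' proteome-wide loop never aborts. A constant response is handled
#' directly (exact least-squares solution, both variances zero). When the
#' random-intercept variance is estimated on the boundary (zero), the
#' reported fixed-effect covariance coincides with the OLS covariance and
#' the fit is flagged `boundary`.
#'
#' @param y Numeric response vector aligned with the design rows
#'   (`design$sample_id` order); `NA` allowed.
#' @param design An `lmm_design` from [build_design].
#' @param protein Protein id carried into the result.
#' @return An `lmm_fit`: list with `protein`, `beta` (named), `vcov`,
#'   `var_patient`, `var_resid`, `n_obs`, `converged`, `boundary`,
#'   `message`.
#' @export
fit_protein_lmm <- function(y, design, protein = NA_character_) {
  stopifnot(inherits(design, "lmm_design"))
  X <- design$X
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(design$X)")
  obs <- !is.na(y)
  failure <- function(msg) {
    structure(list(protein = protein, beta = NULL, vcov = NULL,
                   var_patient = NA_real_, var_resid = NA_real_,
                   n_obs = sum(obs), converged = FALSE, boundary = FALSE,
                   message = msg), class = "lmm_fit")
  }
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  pid <- design$patient[obs]
  p <- ncol(X)
  if (sum(obs) < p + 2) return(failure("too few observations"))
  if (length(unique(pid)) < 2) return(failure("fewer than two patients"))
  if (qr(Xo)$rank < p) return(failure("rank-deficient design after dropout"))
  if (stats::var(yo) == 0) {
    beta <- qr.solve(Xo, yo)
    names(beta) <- colnames(X)
    return(structure(list(protein = protein, beta = beta,
                          vcov = matrix(0, p, p,
                                        dimnames = list(colnames(X),
                                                        colnames(X))),
                          var_patient = 0, var_resid = 0, n_obs = sum(obs),
                          converged = TRUE, boundary = TRUE,
                          message = "constant response"),
                     class = "lmm_fit"))
  }
  dd <- data.frame(.y = yo, .pid = pid)
  dd$.X <- Xo
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(.y ~ 0 + .X + (1 | .pid), data = dd, REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore",
                   # one observation per patient is legitimate here: the
                   # variance components are then identified only through
                   # their sum and beta collapses to OLS
                   check.nobs.vs.nlev = "ignore",
                   check.nobs.vs.nRE = "ignore",
                   check.nobs.vs.rankZ = "ignore"))
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) return(failure(conditionMessage(fit)))
  beta <- lme4::fixef(fit)
  names(beta) <- colnames(X)
  Sigma <- as.matrix(stats::vcov(fit))
  dimnames(Sigma) <- list(colnames(X), colnames(X))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_patient <- vc$vcov[vc$grp == ".pid"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  structure(list(protein = protein, beta = beta, vcov = Sigma,
                 var_patient = var_patient, var_resid = var_resid,
                 n_obs = sum(obs),
                 converged = length(msgs) == 0 ||
                   all(grepl("singular|boundary", msgs, ignore.case = TRUE)),
                 boundary = lme4::isSingular(fit),
                 message = if (length(msgs)) paste(msgs, collapse = "; ")
                           else ""),
            class = "lmm_fit")
}

#' Wald test of a linear contrast of the fixed effects
#'
#' Estimates `c'beta` with standard error `sqrt(c' Sigma c)` and a
#' large-sample two-sided z test. A zero standard error with a nonzero
#' estimate yields `p = 0` with `degenerate = TRUE`; with a zero estimate,
#' `p = 1`.
#'
#' @param fit An `lmm_fit`.
#' @param contrast Numeric contrast vector, `length(beta)`.
#' @param label Contrast label carried into the result.
#' @param family Contrast family label.
#' @return One-row data frame: `protein`, `family`, `label`, `estimate`,
#'   `se`, `z`, `p_raw`, `degenerate`, `converged`.
#' @export
test_contrast <- function(fit, contrast, label = "", family = "") {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged || is.null(fit$beta)) {
    return(data.frame(protein = fit$protein, family = family, label = label,
                      estimate = NA_real_, se = NA_real_, z = NA_real_,
                      p_raw = NA_real_, degenerate = FALSE, converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (length(contrast) != length(fit$beta)) {
    stop("contrast length must match the number of fixed effects")
  }
  est <- sum(contrast * fit$beta)
  v <- drop(t(contrast) %*% fit$vcov %*% contrast)
  se <- sqrt(max(v, 0))
  if (se == 0) {
    z <- if (est == 0) 0 else sign(est) * Inf
    p <- if (est == 0) 1 else 0
    degenerate <- est != 0
  } else {
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    degenerate <- FALSE
  }
  data.frame(protein = fit$protein, family = family, label = label,
             estimate = est, se = se, z = z, p_raw = p,
             degenerate = degenerate, converged = TRUE,
             stringsAsFactors = FALSE)
}

#' Enumerate the four contrast families
#'
#' On the saturated (`interactions = "full"`) design every contrast is a
#' difference of design-cell rows:
#' * `pairwise_pre` — every response pair, within each arm, at
#'   pre-treatment;
#' * `interaction_arm_response` — the arm-by-response
#'   difference-in-differences of every response pair at pre-treatment
#'   (pairs against the reference level reproduce the interaction
#'   coefficients);
#' * `pre_post_within` — post minus pre within each response-by-arm cell;
#' * `interaction_arm_time` — the arm-by-time difference-in-differences
#'   within each response.
#'
#' @param design An `lmm_design` built with `interactions = "full"`.
#' @return List with `contrasts` (matrix, one row per contrast) and
#'   `info` (data frame: `family`, `label`, `response_hi`, `response_lo`,
#'   `response`, `arm`).
#' @export
enumerate_contrasts <- function(design) {
  stopifnot(inherits(design, "lmm_design"))
  if (design$interactions != "full") {
    stop("enumerate_contrasts requires a design with interactions = \"full\"")
  }
  resp <- design$levels$response
  arms <- design$levels$arm
  cell <- function(r, a, t) design_cell_row(design, r, a, t)
  rows <- list(); info <- list()
  add <- function(cvec, family, label, response_hi = NA, response_lo = NA,
                  response = NA, arm = NA) {
    rows[[length(rows) + 1]] <<- cvec
    info[[length(info) + 1]] <<- data.frame(
      family = family, label = label, response_hi = response_hi,
      response_lo = response_lo, response = response, arm = arm,
      stringsAsFactors = FALSE)
  }
  pairs <- utils::combn(resp, 2, simplify = FALSE)
  # family 1: response pair differences at pre, within each arm
  for (a in arms) for (pr in pairs) {
    lo <- pr[1]; hi <- pr[2]   # later factor level minus earlier
    add(cell(hi, a, "pre") - cell(lo, a, "pre"), "pairwise_pre",
        sprintf("%s-%s | %s, pre", hi, lo, a),
        response_hi = hi, response_lo = lo, arm = a)
  }
  # family 2: arm x response difference-in-differences at pre
  for (pr in pairs) {
    lo <- pr[1]; hi <- pr[2]
    d2 <- cell(hi, arms[2], "pre") - cell(lo, arms[2], "pre")
    d1 <- cell(hi, arms[1], "pre") - cell(lo, arms[1], "pre")
    add(d2 - d1, "interaction_arm_response",
        sprintf("(%s-%s) x arm", hi, lo),
        response_hi = hi, response_lo = lo)
  }
  # family 3: post minus pre within each response x arm cell
  for (a in arms) for (r in resp) {
    add(cell(r, a, "post") - cell(r, a, "pre"), "pre_post_within",
        sprintf("post-pre | %s, %s", r, a), response = r, arm = a)
  }
  # family 4: arm x time difference-in-differences within each response
  for (r in resp) {
    d2 <- cell(r, arms[2], "post") - cell(r, arms[2], "pre")
    d1 <- cell(r, arms[1], "post") - cell(r, arms[1], "pre")
    add(d2 - d1, "interaction_arm_time",
        sprintf("(post-pre) x arm | %s", r), response = r)
  }
  list(contrasts = do.call(rbind, rows), info = do.call(rbind, info))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of raw p values in [0, 1]; `NA` allowed
#'   (left `NA`, not counted in the number of tests).
#' @return Adjusted p values, clipped at 1, in the input order.
#' @export
adjust_bh <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (n == 0) return(out)
  o <- ok[order(p[ok])]
  q <- p[o] * n / seq_len(n)
  out[o] <- pmin(1, rev(cummin(rev(q))))
  out
}

#' Run the full per-protein contrast analysis
#'
#' Fits the saturated mixed model to every protein of a normalized
#' matrix, evaluates all four contrast families, and adjusts p values by
#' Benjamini-Hochberg.
#'
#' @param matrix A `normalized_log` [protein_matrix].
#' @param annotation A `sample_annotation` covering the matrix columns.
#' @param reference_levels Passed to [build_design].
#' @param adjust_scope `"family"` (default: BH pooled over all proteins
#'   and contrasts within each family), `"global"` (one pool), or
#'   `"per_label"` (one pool per contrast label).
#' @return A tidy data frame (`contrast_results`): `protein`, `family`,
#'   `label`, `response_hi`, `response_lo`, `response`, `arm`, `estimate`,
#'   `se`, `z`, `p_raw`, `p_adj`, `degenerate`, `converged`, `boundary`.
#' @export
run_contrast_analysis <- function(matrix, annotation,
                                  reference_levels = c(response = "PD",
                                                       arm = "placebo",
                                                       time = "pre"),
                                  adjust_scope = c("family", "global",
                                                   "per_label")) {
  adjust_scope <- match.arg(adjust_scope)
  stopifnot(inherits(matrix, "protein_matrix"))
  if (matrix$state != "normalized_log") {
    stop("expected a normalized_log matrix; run normalize_and_log() first")
  }
  annotation <- as_sample_annotation(annotation)
  missing_samples <- setdiff(annotation$sample_id, colnames(matrix$values))
  if (length(missing_samples)) {
    stop("annotation samples absent from matrix: ",
         paste(utils::head(missing_samples, 5), collapse = ", "))
  }
  design <- build_design(annotation, reference_levels = reference_levels,
                         interactions = "full")
  ctr <- enumerate_contrasts(design)
  vals <- matrix$values[, design$sample_id, drop = FALSE]
  res <- vector("list", nrow(vals))
  for (i in seq_len(nrow(vals))) {
    fit <- fit_protein_lmm(vals[i, ], design, protein = rownames(vals)[i])
    rows <- lapply(seq_len(nrow(ctr$contrasts)), function(j) {
      test_contrast(fit, ctr$contrasts[j, ], label = ctr$info$label[j],
                    family = ctr$info$family[j])
    })
    block <- do.call(rbind, rows)
    block$response_hi <- ctr$info$response_hi
    block$response_lo <- ctr$info$response_lo
    block$response <- ctr$info$response
    block$arm <- ctr$info$arm
    block$boundary <- fit$boundary
    res[[i]] <- block
  }
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  grp <- switch(adjust_scope,
                family = out$family,
                global = rep("all", nrow(out)),
                per_label = paste(out$family, out$label))
  for (g in unique(grp)) {
    idx <- grp == g
    out$p_adj[idx] <- adjust_bh(out$p_raw[idx])
  }
  out <- out[c("protein", "family", "label", "response_hi", "response_lo",
               "response", "arm", "estimate", "se", "z", "p_raw", "p_adj",
               "degenerate", "converged", "boundary")]
  class(out) <- c("contrast_results", "data.frame")
  out
}

#' Write contrast results as tidy CSV
#'
#' @param results A `contrast_results` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contrast_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contrast_results
#' @export
read_contrast_results <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("contrast_results", "data.frame")
  out
}
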
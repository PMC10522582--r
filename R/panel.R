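#' Zero-impute undetected values for selected proteins
#'
#' Replaces missing cells of the listed proteins by 0, leaving every
#' other cell untouched. Mirrors the convention of assigning undetected
#' plasma proteins an expression of zero before prediction.
#'
#' @param matrix A [protein_matrix] (any state).
#' @param proteins Protein ids to impute.
#' @return The matrix with the listed proteins' missing cells set to 0.
#' @export
impute_zero <- function(matrix, proteins) {
  stopifnot(inherits(matrix, "protein_matrix"))
  unknown <- setdiff(proteins, rownames(matrix$values))
  if (length(unknown)) {
    stop("unknown protein id(s): ", paste(unknown, collapse = ", "))
  }
  v <- matrix$values
  rows <- which(rownames(v) %in% proteins)
  sub <- v[rows, , drop = FALSE]
  sub[is.na(sub)] <- 0
  v[rows, ] <- sub
  matrix$values <- v
  matrix
}

#' Panel specification
#'
#' @param proteins Character vector of panel protein ids (>= 1).
#' @param positive Response level(s) defining the positive class, e.g.
#'   `"CR"` or `c("CR", "PR")`.
#' @param rule `"mean_z"` (average per-protein z score over the scored
#'   samples; default) or `"single"` (one protein's expression).
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(proteins, positive = "CR",
                       rule = c("mean_z", "single")) {
  rule <- match.arg(rule)
  stopifnot(length(proteins) >= 1, length(positive) >= 1)
  if (rule == "single" && length(unique(proteins)) > 1) {
    stop("rule \"single\" takes exactly one protein")
  }
  structure(list(proteins = as.character(proteins),
                 positive = as.character(positive), rule = rule),
            class = "panel_spec")
}

#' Score samples with a protein panel
#'
#' For `mean_z`, each panel protein is standardized over the scored
#' samples ((value - mean) / sd, computed on the given columns) and the
#' per-sample average across proteins is returned; a zero-variance
#' protein contributes z = 0 with a warning. For `single`, the protein's
#' expression itself is the score. Markers are pre-treatment predictors,
#' so callers normally pass pre-treatment columns only.
#'
#' @param matrix A [protein_matrix] whose columns are the samples to
#'   score (zero-impute first if the panel proteins have missing cells).
#' @param spec A [panel_spec].
#' @return Named numeric vector of per-sample scores.
#' @export
panel_score <- function(matrix, spec) {
  stopifnot(inherits(matrix, "protein_matrix"), inherits(spec, "panel_spec"))
  unknown <- setdiff(spec$proteins, rownames(matrix$values))
  if (length(unknown)) {
    stop("panel protein(s) absent from matrix: ",
         paste(unknown, collapse = ", "))
  }
  sl <- matrix$values[unique(spec$proteins), , drop = FALSE]  # a panel is a set
  if (anyNA(sl)) {
    stop("panel proteins contain missing cells; apply impute_zero() first")
  }
  if (spec$rule == "single") return(sl[1, ])
  z <- t(apply(sl, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) {
      warning("zero-variance panel protein; its z scores set to 0")
      rep(0, length(x))
    } else (x - mean(x)) / s
  }))
  colMeans(z)
}

#' ROC curve and AUC
#'
#' AUC by pairwise concordance with ties counted one half (the
#' rank-sum / Mann-Whitney statistic); the curve is a threshold sweep
#' over the distinct score values, starting at (0, 0) and ending at
#' (1, 1).
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical (or coercible) positive-class indicators.
#' @return A `roc_result`: list with `auc`, `n_pos`, `n_neg`, and `curve`
#'   (data frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both a positive and a negative sample are required")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1) {
    curve <- rbind(curve, data.frame(fpr = 1, tpr = 1))
  }
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Panel ROC on pre-treatment samples
#'
#' Convenience wrapper: subsets the matrix to pre-treatment samples with
#' a non-NE response, zero-imputes the panel proteins, scores with
#' [panel_score], and computes the ROC against the positive response
#' class.
#'
#' @param matrix A `normalized_log` [protein_matrix].
#' @param annotation A `sample_annotation`.
#' @param spec A [panel_spec].
#' @param arm Optional arm to restrict to (e.g. `"ATRA"`); `NULL` keeps
#'   both arms.
#' @return A `roc_result` with the scores attached as `scores`.
#' @export
panel_roc <- function(matrix, annotation, spec, arm = NULL) {
  annotation <- as_sample_annotation(annotation)
  keep <- annotation$time == "pre" & annotation$response != "NE"
  if (!is.null(arm)) keep <- keep & annotation$arm == arm
  ann <- annotation[keep, , drop = FALSE]
  if (nrow(ann) == 0) stop("no scorable pre-treatment samples")
  sub <- matrix
  sub$values <- sub$values[, ann$sample_id, drop = FALSE]
  sub <- impute_zero(sub, spec$proteins)
  scores <- panel_score(sub, spec)
  out <- roc_auc(scores, ann$response %in% spec$positive)
  out$scores <- scores
  out
}
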
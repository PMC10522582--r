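#' Thresholds for the marker / target decision rules
#'
#' Defaults follow the published rules: a protein is differential if any
#' relevant contrast has raw p < 0.05; it is arm-unique if additionally
#' (adjusted p < 0.05 OR |coefficient| > 1.5 for response markers, > 1.2
#' for treatment targets) AND the matching arm-interaction contrast has
#' p < 0.05.
#'
#' @param raw_p_threshold,adj_p_threshold,interaction_p_threshold
#'   Significance gates, each in (0, 1].
#' @param coef_threshold_markers,coef_threshold_targets Absolute
#'   log2-coefficient gates (> 0).
#' @param interaction_scale Which interaction p gates uniqueness:
#'   `"raw"` (default; the rule names a bare p value where it says
#'   "adjusted" explicitly elsewhere) or `"adjusted"`.
#' @return A `marker_call_config` list.
#' @export
marker_call_config <- function(raw_p_threshold = 0.05,
                               adj_p_threshold = 0.05,
                               coef_threshold_markers = 1.5,
                               coef_threshold_targets = 1.2,
                               interaction_p_threshold = 0.05,
                               interaction_scale = c("raw", "adjusted")) {
  interaction_scale <- match.arg(interaction_scale)
  stopifnot(raw_p_threshold > 0, raw_p_threshold <= 1,
            adj_p_threshold > 0, adj_p_threshold <= 1,
            interaction_p_threshold > 0, interaction_p_threshold <= 1,
            coef_threshold_markers > 0, coef_threshold_targets > 0)
  structure(list(raw_p_threshold = raw_p_threshold,
                 adj_p_threshold = adj_p_threshold,
                 coef_threshold_markers = coef_threshold_markers,
                 coef_threshold_targets = coef_threshold_targets,
                 interaction_p_threshold = interaction_p_threshold,
                 interaction_scale = interaction_scale),
            class = "marker_call_config")
}

empty_calls <- function() {
  data.frame(protein = character(0), call_type = character(0),
             cell = character(0), arm = character(0), label = character(0),
             estimate = numeric(0), direction = character(0),
             p_raw = numeric(0), p_adj = numeric(0),
             interaction_label = character(0), interaction_p = numeric(0),
             fired_raw_p = logical(0), fired_adj_p = logical(0),
             fired_coef = logical(0), fired_interaction_p = logical(0),
             stringsAsFactors = FALSE)
}

# cell and direction of a pairwise (hi - lo) contrast: the protein is
# called "up" in whichever response group it is higher in
pairwise_cell <- function(rows) {
  up_hi <- rows$estimate >= 0
  list(cell = ifelse(up_hi, rows$response_hi, rows$response_lo),
       direction = rep("up", nrow(rows)))
}

#' Call differentially expressed proteins within one contrast family
#'
#' Flags every (protein, contrast) with raw p below the threshold.
#'
#' @param results A `contrast_results` data frame.
#' @param family One of `pairwise_pre`, `interaction_arm_response`,
#'   `pre_post_within`, `interaction_arm_time`.
#' @param config A [marker_call_config].
#' @return A marker-call data frame (possibly empty): one row per
#'   triggering contrast with the rule components that fired.
#' @export
call_differential <- function(results, family,
                              config = marker_call_config()) {
  if (!family %in% results$family) {
    if (nrow(results) == 0) return(empty_calls())
    stop("results do not contain family ", family)
  }
  rows <- results[results$family == family & results$converged &
                    !is.na(results$p_raw) &
                    results$p_raw < config$raw_p_threshold, , drop = FALSE]
  if (nrow(rows) == 0) return(empty_calls())
  if (family %in% c("pairwise_pre", "interaction_arm_response")) {
    cd <- pairwise_cell(rows)
    call_type <- "differential_pre"
  } else {
    cd <- list(cell = rows$response,
               direction = ifelse(rows$estimate >= 0, "up", "down"))
    call_type <- "differential_prepost"
  }
  data.frame(protein = rows$protein, call_type = call_type, cell = cd$cell,
             arm = rows$arm, label = rows$label, estimate = rows$estimate,
             direction = cd$direction, p_raw = rows$p_raw,
             p_adj = rows$p_adj, interaction_label = NA_character_,
             interaction_p = NA_real_, fired_raw_p = TRUE,
             fired_adj_p = !is.na(rows$p_adj) &
               rows$p_adj < config$adj_p_threshold,
             fired_coef = NA, fired_interaction_p = NA,
             row.names = NULL, stringsAsFactors = FALSE)
}

# shared compound rule: candidate family gated by an interaction family
unique_calls <- function(results, config, candidate_family,
                         interaction_family, coef_threshold, target_arm,
                         call_type) {
  for (f in c(candidate_family, interaction_family)) {
    if (!f %in% results$family) stop("results lack family ", f)
  }
  cand <- results[results$family == candidate_family & results$converged &
                    results$arm == target_arm, , drop = FALSE]
  inter <- results[results$family == interaction_family &
                     results$converged, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_calls())
  if (candidate_family == "pairwise_pre") {
    key_c <- paste(cand$protein, cand$response_hi, cand$response_lo)
    key_i <- paste(inter$protein, inter$response_hi, inter$response_lo)
  } else {
    key_c <- paste(cand$protein, cand$response)
    key_i <- paste(inter$protein, inter$response)
  }
  m <- match(key_c, key_i)
  ip <- if (config$interaction_scale == "raw") inter$p_raw[m] else
    inter$p_adj[m]
  fired_raw <- !is.na(cand$p_raw) & cand$p_raw < config$raw_p_threshold
  fired_adj <- !is.na(cand$p_adj) & cand$p_adj < config$adj_p_threshold
  fired_coef <- !is.na(cand$estimate) & abs(cand$estimate) > coef_threshold
  fired_int <- !is.na(ip) & ip < config$interaction_p_threshold
  keep <- fired_raw & (fired_adj | fired_coef) & fired_int
  rows <- cand[keep, , drop = FALSE]
  if (nrow(rows) == 0) return(empty_calls())
  if (candidate_family == "pairwise_pre") {
    cd <- pairwise_cell(rows)
  } else {
    cd <- list(cell = rows$response,
               direction = ifelse(rows$estimate >= 0, "up", "down"))
  }
  data.frame(protein = rows$protein, call_type = call_type, cell = cd$cell,
             arm = rows$arm, label = rows$label, estimate = rows$estimate,
             direction = cd$direction, p_raw = rows$p_raw,
             p_adj = rows$p_adj,
             interaction_label = inter$label[m][keep],
             interaction_p = ip[keep], fired_raw_p = TRUE,
             fired_adj_p = fired_adj[keep], fired_coef = fired_coef[keep],
             fired_interaction_p = TRUE, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call arm-unique response markers
#'
#' A protein is a unique response marker of the target arm if, for some
#' pre-treatment response contrast in that arm: raw p < 0.05 AND
#' (adjusted p < 0.05 OR |coefficient| > 1.5) AND the arm-by-response
#' interaction contrast of the same response pair has p < 0.05. The call
#' records the response cell the protein is elevated in.
#'
#' @param results A `contrast_results` data frame containing the
#'   `pairwise_pre` and `interaction_arm_response` families.
#' @param config A [marker_call_config].
#' @param target_arm Arm whose uniqueness is tested (default `"ATRA"`).
#' @return A marker-call data frame with `call_type = "unique_marker"`.
#' @export
call_unique_markers <- function(results, config = marker_call_config(),
                                target_arm = "ATRA") {
  unique_calls(results, config,
               candidate_family = "pairwise_pre",
               interaction_family = "interaction_arm_response",
               coef_threshold = config$coef_threshold_markers,
               target_arm = target_arm, call_type = "unique_marker")
}

#' Call arm-unique treatment targets
#'
#' Same compound structure as [call_unique_markers] over the pre/post
#' families: raw p < 0.05 on a post-minus-pre contrast in the target arm,
#' (adjusted p < 0.05 OR |coefficient| > 1.2), and the arm-by-time
#' interaction within the same response evaluation at p < 0.05.
#'
#' @inheritParams call_unique_markers
#' @return A marker-call data frame with `call_type = "unique_target"`.
#' @export
call_unique_targets <- function(results, config = marker_call_config(),
                                target_arm = "ATRA") {
  unique_calls(results, config,
               candidate_family = "pre_post_within",
               interaction_family = "interaction_arm_time",
               coef_threshold = config$coef_threshold_targets,
               target_arm = target_arm, call_type = "unique_target")
}

#' Write marker calls as CSV
#'
#' One row per (protein, call type, cell) with the rule components fired.
#'
#' @param calls A marker-call data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_marker_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE)
  invisible(path)
}
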
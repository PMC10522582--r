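#' Protein abundance matrix
#'
#' Container for a proteins x samples abundance grid with explicit
#' missingness (`NA` = undetected) and a state flag distinguishing raw
#' spectral counts from normalized log-scale expression values.
#'
#' @param values Numeric matrix, proteins in rows and samples in columns.
#'   Row and column names are required (protein ids, sample ids). `NA`
#'   marks a cell where the protein was not detected in that sample.
#' @param state Either `"raw_counts"` (non-negative counts) or
#'   `"normalized_log"` (log-scale relative abundances).
#' @param log_base,pseudocount Bookkeeping for the `normalized_log` state:
#'   the log base and the pseudocount added before the log. Ignored (and
#'   stored as `NA`) for raw matrices.
#'
#' @return An object of class `protein_matrix`: a list with elements
#'   `values`, `state`, `log_base`, `pseudocount`.
#' @export
protein_matrix <- function(values, state = c("raw_counts", "normalized_log"),
                           log_base = NA_real_, pseudocount = NA_real_) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (proteins x samples)")
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("`values` must have protein row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated protein ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  if (state == "raw_counts" && any(values < 0, na.rm = TRUE)) {
    stop("raw_counts state admits only non-negative or missing entries")
  }
  structure(
    list(values = values, state = state,
         log_base = if (state == "normalized_log") log_base else NA_real_,
         pseudocount = if (state == "normalized_log") pseudocount else NA_real_),
    class = "protein_matrix"
  )
}

#' @export
print.protein_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<protein_matrix> %d proteins x %d samples [%s]\n",
              nrow(v), ncol(v), x$state))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
  if (x$state == "normalized_log") {
    cat(sprintf("  log base %s, pseudocount %g\n", format(x$log_base),
                x$pseudocount))
  }
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

RESPONSE_LEVELS <- c("PD", "SD", "PR", "CR", "NE")
ARM_LEVELS <- c("placebo", "ATRA")
TIME_LEVELS <- c("pre", "post")

#' Validate a sample annotation table
#'
#' The annotation drives the mixed-model design: one row per proteome
#' sample with the patient it came from, the randomization arm, the time
#' point relative to treatment, and the patient's overall response
#' evaluation.
#'
#' @param annotation A data frame with columns `sample_id`, `patient_id`,
#'   `arm` (`"ATRA"` or `"placebo"`), `time` (`"pre"` or `"post"`), and
#'   `response` (`"PD"`, `"SD"`, `"PR"`, `"CR"`, `"NE"`).
#'
#' @return The validated data frame with factor columns in canonical level
#'   order, invisibly classed as `sample_annotation`.
#' @export
as_sample_annotation <- function(annotation) {
  req <- c("sample_id", "patient_id", "arm", "time", "response")
  missing_cols <- setdiff(req, names(annotation))
  if (length(missing_cols)) {
    stop("annotation lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  ann <- as.data.frame(annotation)[req]
  ann$sample_id <- as.character(ann$sample_id)
  ann$patient_id <- as.character(ann$patient_id)
  chk <- function(col, levels) {
    bad <- setdiff(unique(as.character(ann[[col]])), levels)
    if (length(bad)) {
      stop(sprintf("invalid %s value(s): %s", col, paste(bad, collapse = ", ")))
    }
    factor(as.character(ann[[col]]), levels = levels)
  }
  ann$arm <- chk("arm", ARM_LEVELS)
  ann$time <- chk("time", TIME_LEVELS)
  ann$response <- chk("response", RESPONSE_LEVELS)
  if (anyDuplicated(ann$sample_id)) stop("duplicated sample ids")
  if (anyDuplicated(ann[c("patient_id", "time")])) {
    stop("each (patient, time) pair may occur at most once")
  }
  per_pat <- unique(ann[c("patient_id", "arm", "response")])
  if (anyDuplicated(per_pat$patient_id)) {
    stop("each patient must have exactly one arm and one response")
  }
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

#' Read / write a protein matrix as TSV
#'
#' Plain-text round trip: proteins in rows, samples in columns, first
#' column `protein`, empty fields for missing cells.
#'
#' @param matrix A [protein_matrix].
#' @param path File path.
#' @param state State flag to assign on read (the file itself stores only
#'   the grid).
#' @return `write_protein_matrix` returns `path` invisibly;
#'   `read_protein_matrix` returns a [protein_matrix].
#' @export
write_protein_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "protein_matrix"))
  df <- data.frame(protein = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_protein_matrix
#' @export
read_protein_matrix <- function(path, state = c("raw_counts", "normalized_log")) {
  state <- match.arg(state)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  protein_matrix(m, state = state,
                 log_base = if (state == "normalized_log") 2 else NA_real_,
                 pseudocount = if (state == "normalized_log") 1e-6 else NA_real_)
}
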
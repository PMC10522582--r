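#' Filter proteins by detection
#'
#' Drops proteins undetected in too many samples. "Undetected" means a
#' missing cell; optionally observed zeros count as undetected too.
#'
#' @param matrix A raw-state [protein_matrix].
#' @param max_missing_samples Retain a protein iff its number of
#'   undetected samples is `<=` this threshold (default 40).
#' @param zero_is_missing Treat observed zero counts as undetected.
#' @return The filtered [protein_matrix]; row order preserved.
#' @export
filter_undetected <- function(matrix, max_missing_samples = 40L,
                              zero_is_missing = FALSE) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (matrix$state != "raw_counts") stop("expected a raw_counts matrix")
  if (length(max_missing_samples) != 1 || is.na(max_missing_samples) ||
      max_missing_samples < 0) {
    stop("max_missing_samples must be a single non-negative integer")
  }
  v <- matrix$values
  und <- is.na(v)
  if (zero_is_missing) und <- und | (!is.na(v) & v == 0)
  keep <- rowSums(und) <= max_missing_samples
  protein_matrix(v[keep, , drop = FALSE], state = "raw_counts")
}

#' Total-count normalization and log transform
#'
#' Divides every observed cell by its sample's total observed spectral
#' count (missing cells are excluded from the total and stay missing),
#' then applies `log2(x + pseudocount)`. Per-sample observed fractions sum
#' to 1 before the log.
#'
#' @param matrix A raw-state [protein_matrix].
#' @param pseudocount Added before the log to guard observed zeros.
#' @param log_base Logarithm base.
#' @return A `normalized_log`-state [protein_matrix].
#' @export
normalize_and_log <- function(matrix, pseudocount = 1e-6, log_base = 2) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (matrix$state != "raw_counts") stop("expected a raw_counts matrix")
  v <- matrix$values
  totals <- colSums(v, na.rm = TRUE)
  n_obs <- colSums(!is.na(v))
  bad <- n_obs == 0 | totals <= 0
  if (any(bad)) {
    stop("sample(s) with no positive observed total: ",
         paste(colnames(v)[bad], collapse = ", "))
  }
  frac <- sweep(v, 2, totals, "/")
  out <- log(frac + pseudocount, base = log_base)
  protein_matrix(out, state = "normalized_log", log_base = log_base,
                 pseudocount = pseudocount)
}
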
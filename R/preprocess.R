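#' Counts per million
#'
#' Scales each sample (column) of a count matrix to counts per million
#' mapped reads: `cpm[g, s] = counts[g, s] / libsize[s] * 1e6`.
#'
#' @param counts A wide count table (first column `feature_id`, one numeric
#'   column per sample) or a nonnegative matrix with feature rownames.
#' @return A tibble in the same wide shape, with CPM values.
#' @export
#' @examples
#' counts <- tibble::tibble(feature_id = c("a", "b"), s1 = c(3, 7))
#' compute_cpm(counts) # library size 10: a -> 3e5, b -> 7e5
compute_cpm <- function(counts) {
  mat <- as_feature_matrix(counts, "counts")
  check_counts(mat)
  lib <- colSums(mat)
  zero <- lib <= 0
  if (any(zero)) {
    abort(sprintf(
      "Zero library size in sample(s): %s",
      paste(colnames(mat)[zero], collapse = ", ")
    ))
  }
  as_feature_tibble(sweep(mat, 2L, lib, "/") * 1e6)
}

check_counts <- function(mat) {
  if (any(!is.finite(mat))) abort("Counts must be finite.")
  if (any(mat < 0)) abort("Counts must be nonnegative.")
  invisible(mat)
}

#' Filter features by CPM expression level
#'
#' Keeps features with CPM at or above `cpm_min` in at least `frac_samples`
#' of samples, irrespective of timepoint. The boundary is inclusive: with
#' 4 samples and `frac_samples = 0.75`, exactly 3 passing samples keeps the
#' feature. Feature order is preserved.
#'
#' @inheritParams compute_cpm
#' @param cpm_min Minimum CPM counted as expressed (default 0.5).
#' @param frac_samples Minimum fraction of samples at or above `cpm_min`
#'   (default 0.75).
#' @return The filtered count table as a tibble.
#' @export
filter_low_expression <- function(counts, cpm_min = 0.5, frac_samples = 0.75) {
  if (!is.numeric(cpm_min) || length(cpm_min) != 1L || !is.finite(cpm_min) ||
      cpm_min < 0) {
    abort("`cpm_min` must be a single nonnegative number.")
  }
  if (!is.numeric(frac_samples) || length(frac_samples) != 1L ||
      !is.finite(frac_samples) || frac_samples <= 0 || frac_samples > 1) {
    abort("`frac_samples` must be in (0, 1].")
  }
  mat <- as_feature_matrix(counts, "counts")
  check_counts(mat)
  cpm <- as_feature_matrix(compute_cpm(mat))
  frac_pass <- rowMeans(cpm >= cpm_min)
  keep <- frac_pass >= frac_samples
  if (!any(keep)) {
    warn("No features pass the expression filter; returning an empty table.")
  }
  as_feature_tibble(mat[keep, , drop = FALSE])
}

#' Replace zero counts by the feature's minimum nonzero count
#'
#' For each feature with at least one nonzero count, zero entries are set to
#' the minimum of that feature's nonzero counts across samples, so later
#' log transformation does not produce unrealistically low values. Features
#' with all-zero counts are left unchanged with a warning (the expression
#' filter removes them in the default pipeline).
#'
#' @inheritParams compute_cpm
#' @return A tibble in the same wide shape.
#' @export
impute_zero_counts <- function(counts) {
  mat <- as_feature_matrix(counts, "counts")
  check_counts(mat)
  all_zero <- rowSums(mat > 0) == 0L
  if (any(all_zero)) {
    warn(sprintf(
      "%d feature(s) have all-zero counts and were left unchanged.",
      sum(all_zero)
    ))
  }
  for (g in which(!all_zero)) {
    row <- mat[g, ]
    if (any(row == 0)) {
      mat[g, row == 0] <- min(row[row > 0])
    }
  }
  as_feature_tibble(mat)
}

#' Log2 counts per million
#'
#' Computes `log2(CPM + pseudocount)` for every entry.
#'
#' @inheritParams compute_cpm
#' @param pseudocount Nonnegative offset added before the log (default 1).
#' @return A tibble of log2(CPM + pseudocount) values.
#' @export
log_cpm <- function(counts, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount < 0) {
    abort("`pseudocount` must be a single nonnegative number.")
  }
  cpm <- as_feature_matrix(compute_cpm(counts))
  as_feature_tibble(log2(cpm + pseudocount))
}

#' Standard count preprocessing pipeline
#'
#' Applies, in order: the CPM expression filter on the original counts,
#' zero-count replacement, and the log2-CPM transform.
#'
#' @inheritParams filter_low_expression
#' @inheritParams log_cpm
#' @return A tibble of log-scale expression values for the kept features.
#' @export
prepare_counts <- function(counts, cpm_min = 0.5, frac_samples = 0.75,
                           pseudocount = 1) {
  counts |>
    filter_low_expression(cpm_min = cpm_min, frac_samples = frac_samples) |>
    impute_zero_counts() |>
    log_cpm(pseudocount = pseudocount)
}
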
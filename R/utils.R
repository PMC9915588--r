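#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats coef quantile rnorm runif sd var median setNames
NULL

# Convert a wide feature table (first column = feature id) or a matrix with
# rownames into a numeric matrix with feature ids as rownames.
as_feature_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      rownames(x) <- paste0("feature_", seq_len(nrow(x)))
    }
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame or a matrix.", arg))
  }
  if (ncol(x) < 2L) {
    abort(sprintf("`%s` must have a feature-id column plus sample columns.", arg))
  }
  ids <- as.character(x[[1L]])
  if (anyDuplicated(ids)) {
    abort(sprintf("Feature ids in `%s` must be unique.", arg))
  }
  mat <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    abort(sprintf("Sample columns of `%s` must all be numeric.", arg))
  }
  rownames(mat) <- ids
  mat
}

as_feature_tibble <- function(mat) {
  out <- as_tibble(mat, .name_repair = "minimal")
  dplyr::bind_cols(tibble(feature_id = rownames(mat)), out)
}

check_metadata <- function(metadata, sample_ids = NULL) {
  if (!is.data.frame(metadata)) {
    abort("`metadata` must be a data frame.")
  }
  for (col in c("sample_id", "time")) {
    if (!col %in% names(metadata)) {
      abort(sprintf("`metadata` is missing required column '%s'.", col))
    }
  }
  if (!is.numeric(metadata$time) || any(!is.finite(metadata$time))) {
    abort("`metadata$time` must be finite numeric (hours).")
  }
  if (anyDuplicated(metadata$sample_id)) {
    abort("`metadata$sample_id` must be unique.")
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, metadata$sample_id)
    if (length(missing)) {
      abort(sprintf(
        "Samples missing from metadata: %s",
        paste(utils::head(missing, 5L), collapse = ", ")
      ))
    }
    metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  }
  metadata
}

#' Read an expression or count matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' The delimiter is inferred from the file extension (`.csv` vs `.tsv`/other).
#'
#' @param path Path to a delimited text file.
#' @return A tibble with a `feature_id` column followed by numeric sample
#'   columns.
#' @export
read_expression_matrix <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  x <- reader(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1L] <- "feature_id"
  x
}

#' Read sample metadata from CSV
#'
#' Requires columns `sample_id` and `time` (hours); any further columns are
#' treated as covariates.
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_metadata(md)
}

#' Write a wide feature table as TSV
#'
#' @param x A tibble or matrix (rownames become the feature-id column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  if (is.matrix(x)) x <- as_feature_tibble(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
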
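#' Construct and validate a miRNA read-count matrix
#'
#' The count matrix is the central data structure of the discovery phase:
#' an integer matrix with one row per mature miRNA and one column per
#' sample, where entry (i, j) is the number of reads unambiguously
#' assigned to miRNA i in sample j.
#'
#' @param counts numeric matrix of non-negative integers, rows = miRNAs,
#'   columns = samples. Must carry row and column names (or supply
#'   `mirna_ids` / `sample_ids`).
#' @param mirna_ids,sample_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return an integer matrix of class `count_matrix` with unique row and
#'   column names.
#' @export
count_matrix <- function(counts, mirna_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(mirna_ids) || is.null(sample_ids))
    input_error("count matrix needs miRNA (row) and sample (column) ids")
  rownames(counts) <- as.character(mirna_ids)
  colnames(counts) <- as.character(sample_ids)
  validate_count_matrix(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_matrix", class(counts))
  counts
}

validate_count_matrix <- function(counts) {
  if (anyDuplicated(rownames(counts)))
    input_error(sprintf("duplicate miRNA id: %s",
                        rownames(counts)[duplicated(rownames(counts))][1]))
  if (anyDuplicated(colnames(counts)))
    input_error(sprintf("duplicate sample id: %s",
                        colnames(counts)[duplicated(colnames(counts))][1]))
  if (!is.numeric(counts) || anyNA(counts))
    input_error("counts must be numeric with no missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    input_error(sprintf(
      "counts must be non-negative integers; offending entry at miRNA '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  invisible(counts)
}

#' Read a count matrix from a tab-separated file
#'
#' Expects a header row of sample ids and a first column of miRNA ids;
#' all remaining cells are non-negative integer read counts.
#'
#' @param path path to a TSV file.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) input_error("count TSV needs an id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    input_error("non-numeric count values in count TSV")
  count_matrix(m, mirna_ids = ids, sample_ids = colnames(df)[-1])
}

#' Write a count matrix as a tab-separated file
#'
#' @param m a [count_matrix()].
#' @param path output path.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(mirna_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate per-sample cohort metadata
#'
#' @param df data.frame with columns `sample_id`, `class` (one of
#'   [BC_CLASSES]), `age` (years), `smoking` (one of [SMOKING_LEVELS]) and
#'   optionally `batch`.
#' @param case_normalize if `TRUE`, class and smoking labels are matched
#'   case-insensitively and rewritten to the canonical spelling.
#' @return the validated data.frame with `class` and `smoking` as factors,
#'   classed `cohort_metadata`.
#' @export
cohort_metadata <- function(df, case_normalize = FALSE) {
  need <- c("sample_id", "class", "age", "smoking")
  miss <- setdiff(need, names(df))
  if (length(miss))
    input_error(paste("metadata missing column(s):",
                      paste(miss, collapse = ", ")))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    input_error(sprintf("duplicate sample_id '%s' in metadata",
                        df$sample_id[duplicated(df$sample_id)][1]))
  norm <- function(x, levels, what) {
    x <- as.character(x)
    if (case_normalize) {
      idx <- match(tolower(x), tolower(levels))
      x <- ifelse(is.na(idx), x, levels[idx])
    }
    bad <- setdiff(unique(x), levels)
    if (length(bad))
      input_error(sprintf("unknown %s level '%s'", what, bad[1]))
    factor(x, levels = levels)
  }
  df$class <- norm(df$class, BC_CLASSES, "class")
  df$smoking <- norm(df$smoking, SMOKING_LEVELS, "smoking")
  df$age <- as.numeric(df$age)
  if (anyNA(df$age)) input_error("non-numeric age in metadata")
  if (any(df$age < 30 | df$age > 100))
    warning("age outside the plausible 30-100 range for ",
            sum(df$age < 30 | df$age > 100), " sample(s)")
  if (!is.null(df$batch)) df$batch <- factor(df$batch)
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Read cohort metadata from a tab-separated file
#'
#' @inheritParams cohort_metadata
#' @param path path to a TSV with columns sample_id, class, age, smoking
#'   and optionally batch.
#' @export
read_metadata <- function(path, case_normalize = FALSE) {
  cohort_metadata(utils::read.delim(path, stringsAsFactors = FALSE),
                  case_normalize = case_normalize)
}

#' Write cohort metadata as a tab-separated file
#' @param meta a [cohort_metadata()] table.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Check that metadata covers exactly the samples of a count matrix and
# return it reordered to the matrix's column order.
align_metadata <- function(m, meta) {
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx))
    input_error(sprintf("sample '%s' missing from metadata",
                        colnames(m)[which(is.na(idx))[1]]))
  meta[idx, , drop = FALSE]
}

#' @export
`[.count_matrix` <- function(x, ..., drop = FALSE) {
  y <- NextMethod()
  if (is.matrix(y)) class(y) <- oldClass(x)
  y
}

#' Remove miRNAs with low total read count
#'
#' Discovery-phase filter: a miRNA is kept when its read total summed over
#' all samples is at least `min_total` (inclusive). Row order is
#' preserved.
#'
#' @param m a [count_matrix()].
#' @param min_total minimum summed count across all samples (default 20).
#' @return the filtered `count_matrix`.
#' @export
filter_low_counts <- function(m, min_total = 20) {
  keep <- rowSums(m) >= min_total
  m[keep, , drop = FALSE]
}

#' Mean raw read count of one miRNA
#'
#' The arithmetic mean of unnormalized counts across all samples; this is
#' the abundance figure the candidate filter (mean >= 300) operates on.
#'
#' @param m a [count_matrix()].
#' @param mirna_id a single miRNA id present in `m`.
#' @export
mean_read_count <- function(m, mirna_id) {
  if (!mirna_id %in% rownames(m))
    input_error(sprintf("unknown miRNA id '%s'", mirna_id))
  mean(m[mirna_id, ])
}
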
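#' Construct a feature table for one batch
#'
#' A `feature_table` holds the intensity matrix of one measurement batch
#' (samples in rows, features in columns) together with its per-sample
#' metadata. One table always represents exactly one batch: multi-batch
#' studies are collections of tables, which keeps batch provenance explicit
#' (one MS target plate, one acquisition day = one table).
#'
#' @param values numeric matrix, `n_samples x n_features`; no missing entries.
#' @param feature_ids character vector of feature identifiers (for example
#'   m/z bins encoded as decimal strings). Defaults to column names of
#'   `values` or `f1, f2, ...`.
#' @param sample_ids unique character identifiers, one per row.
#' @param subject_ids character identifiers mapping samples to subjects
#'   (many samples may share a subject; replicate measurements are typical
#'   for MALDI MS acquisitions).
#' @param batch_id single string naming the batch.
#' @param labels optional integer vector in `{0, 1}` aligned to samples
#'   (1 = case, 0 = control), or `NULL` when the batch is unlabeled.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, feature_ids = NULL, sample_ids = NULL,
                          subject_ids = NULL, batch_id = "batch1",
                          labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); p <- ncol(values)
  if (n < 1L || p < 1L) abort_ba("feature table must have at least one sample and one feature")
  if (anyNA(values)) abort_ba("feature table values contain missing entries")
  feature_ids <- as.character(feature_ids %||% colnames(values) %||% paste0("f", seq_len(p)))
  sample_ids <- as.character(sample_ids %||% rownames(values) %||% paste0("s", seq_len(n)))
  subject_ids <- as.character(subject_ids %||% sample_ids)
  if (length(feature_ids) != p) abort_ba("feature_ids length (%d) != n_features (%d)", length(feature_ids), p)
  if (length(sample_ids) != n) abort_ba("sample_ids length (%d) != n_samples (%d)", length(sample_ids), n)
  if (anyDuplicated(sample_ids)) abort_ba("sample_ids must be unique")
  if (length(subject_ids) != n) abort_ba("subject_ids length (%d) != n_samples (%d)", length(subject_ids), n)
  if (any(!nzchar(subject_ids))) abort_ba("subject_ids must be non-empty strings")
  if (length(batch_id) != 1L || !nzchar(batch_id)) abort_ba("batch_id must be a single non-empty string")
  if (!is.null(labels)) {
    if (length(labels) != n) abort_ba("labels length (%d) != n_samples (%d)", length(labels), n)
    labels <- as.integer(labels)
    if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
      abort_ba("labels must be binary 0/1 with no missing values")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, feature_ids = feature_ids, sample_ids = sample_ids,
         subject_ids = subject_ids, batch_id = as.character(batch_id),
         labels = labels),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> batch '%s': %d samples x %d features, %d subjects, labels %s\n",
              x$batch_id, nrow(x$values), ncol(x$values),
              length(unique(x$subject_ids)),
              if (is.null(x$labels)) "absent"
              else sprintf("present (%d/%d positive)", sum(x$labels), length(x$labels))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset the samples of a feature table
#' @param table a [feature_table()].
#' @param idx integer or logical row index.
#' @return A `feature_table` with the selected samples, in index order.
#' @export
subset_samples <- function(table, idx) {
  stopifnot(inherits(table, "feature_table"))
  feature_table(table$values[idx, , drop = FALSE],
                feature_ids = table$feature_ids,
                sample_ids = table$sample_ids[idx],
                subject_ids = table$subject_ids[idx],
                batch_id = table$batch_id,
                labels = if (is.null(table$labels)) NULL else table$labels[idx])
}

#' Default schema describing metadata columns of a delimited feature file
#'
#' @param sample_col,subject_col,batch_col column names of the sample-,
#'   subject- and batch-identifier columns.
#' @param label_col name of the optional binary label column, or `NULL`.
#' @return A named list usable as the `schema` argument of
#'   [read_feature_table()].
#' @export
table_schema <- function(sample_col = "sample", subject_col = "subject",
                         batch_col = "batch", label_col = "label") {
  list(sample_col = sample_col, subject_col = subject_col,
       batch_col = batch_col, label_col = label_col)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a feature table from a delimited text file
#'
#' The file must contain a header row; the schema names the metadata columns
#' and every remaining column is parsed as a numeric feature. A file must
#' contain a single batch; files mixing batches are rejected with an
#' instruction to split them.
#'
#' @param path path to a CSV/TSV file (UTF-8).
#' @param schema list as returned by [table_schema()]; `label_col` may be
#'   absent from the file, in which case the table is unlabeled.
#' @param delim field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param impute missing-value policy: `"reject"` (default; complete matrices
#'   are assumed downstream) or `"mean"` for per-feature mean imputation.
#' @return A validated [feature_table()] with row and feature order preserved.
#' @export
read_feature_table <- function(path, schema = table_schema(), delim = NULL,
                               impute = c("reject", "mean")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) abort_ba("file not found: %s", path)
  delim <- delim %||% detect_delim(path)
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  for (col in c(schema$sample_col, schema$subject_col, schema$batch_col)) {
    if (!col %in% names(df))
      abort_ba("schema error in %s: required column '%s' is missing", path, col)
  }
  has_label <- !is.null(schema$label_col) && schema$label_col %in% names(df)
  meta_cols <- c(schema$sample_col, schema$subject_col, schema$batch_col,
                 if (has_label) schema$label_col)
  feat_cols <- setdiff(names(df), meta_cols)
  if (length(feat_cols) == 0L) abort_ba("no feature columns found in %s", path)
  batches <- unique(as.character(df[[schema$batch_col]]))
  if (length(batches) != 1L)
    abort_ba("file %s mixes %d batch IDs (%s); split it into one file per batch",
             path, length(batches), paste(batches, collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(feat_cols),
                 dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    col <- df[[feat_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(as.character(col))))
    if (length(bad))
      abort_ba("non-numeric value '%s' in feature column '%s', row %d of %s",
               col[bad[1L]], feat_cols[j], bad[1L], path)
    vals[, j] <- num
  }
  if (anyNA(vals)) {
    if (impute == "reject") {
      miss <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      abort_ba("missing value in feature column '%s', row %d of %s (use impute = \"mean\" to mean-impute)",
               feat_cols[miss[2L]], miss[1L], path)
    }
    for (j in seq_len(ncol(vals))) {
      nas <- is.na(vals[, j])
      if (any(nas)) vals[nas, j] <- mean(vals[!nas, j])
    }
  }
  feature_table(vals,
                feature_ids = feat_cols,
                sample_ids = as.character(df[[schema$sample_col]]),
                subject_ids = as.character(df[[schema$subject_col]]),
                batch_id = batches,
                labels = if (has_label) df[[schema$label_col]] else NULL)
}

#' Write a feature table to a delimited text file
#'
#' The written file round-trips through [read_feature_table()] with at least
#' 15 significant digits of numeric fidelity.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param schema metadata column names, as in [read_feature_table()].
#' @param delim field delimiter (default comma).
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, schema = table_schema(),
                                delim = ",") {
  stopifnot(inherits(table, "feature_table"))
  meta <- data.frame(table$sample_ids, table$subject_ids,
                     rep(table$batch_id, nrow(table$values)),
                     stringsAsFactors = FALSE)
  names(meta) <- c(schema$sample_col, schema$subject_col, schema$batch_col)
  if (!is.null(table$labels)) {
    meta[[schema$label_col %||% "label"]] <- table$labels
  }
  vals <- as.data.frame(table$values)
  names(vals) <- table$feature_ids
  out <- cbind(meta, vals)
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort_ba("failed to write feature table to %s: %s",
                            path, conditionMessage(ok))
  invisible(path)
}

#' QC rule for feature filtering
#'
#' Features are kept when their signal-to-noise ratio exceeds
#' `snr_threshold` and their relative standard deviation (RSD = sd/mean over
#' replicate measurements) satisfies the configured direction. Note the
#' direction carefully: conventional QC keeps features whose RSD stays
#' *below* a ceiling (reproducible signals), while the `keep_above` default
#' here screens for informative, *varying* signals, as some MS acquisition
#' protocols specify. Choose the direction deliberately for your data.
#'
#' @param snr_threshold positive signal-to-noise cutoff (default 3; strict
#'   `>` comparison).
#' @param rsd_threshold positive RSD cutoff as a fraction (default 0.05,
#'   i.e. 5%; strict comparison).
#' @param rsd_direction `"keep_above"` (default) or `"keep_below"`.
#' @return An object of class `qc_rule`.
#' @export
qc_rule <- function(snr_threshold = 3, rsd_threshold = 0.05,
                    rsd_direction = c("keep_above", "keep_below")) {
  rsd_direction <- match.arg(rsd_direction)
  if (!is.numeric(snr_threshold) || snr_threshold <= 0)
    abort_ba("snr_threshold must be positive")
  if (!is.numeric(rsd_threshold) || rsd_threshold <= 0)
    abort_ba("rsd_threshold must be positive")
  structure(list(snr_threshold = snr_threshold,
                 rsd_threshold = rsd_threshold,
                 rsd_direction = rsd_direction),
            class = "qc_rule")
}

#' Filter features by signal-to-noise ratio and RSD
#'
#' @param per_feature_snr numeric vector of per-feature signal-to-noise
#'   ratios.
#' @param per_feature_rsd numeric vector of per-feature relative standard
#'   deviations (fractions), aligned with `per_feature_snr`.
#' @param rule a [qc_rule()].
#' @return Logical keep-mask of the same length: `TRUE` for features with
#'   `snr > snr_threshold` and the RSD condition holding in the configured
#'   direction.
#' @export
qc_filter_features <- function(per_feature_snr, per_feature_rsd,
                               rule = qc_rule()) {
  stopifnot(inherits(rule, "qc_rule"))
  if (length(per_feature_snr) != length(per_feature_rsd))
    abort_ba("SNR and RSD vectors must have equal length (%d vs %d)",
             length(per_feature_snr), length(per_feature_rsd))
  snr_ok <- per_feature_snr > rule$snr_threshold
  rsd_ok <- if (rule$rsd_direction == "keep_above")
    per_feature_rsd > rule$rsd_threshold
  else
    per_feature_rsd < rule$rsd_threshold
  snr_ok & rsd_ok
}
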
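#' Construct a feature-by-sample count table
#'
#' The universal input of the pipeline: an integer matrix of sequence
#' (ESV/OTU) counts with features as rows and samples as columns, plus an
#' optional semicolon-ranked taxonomy string per feature.
#'
#' @param counts Non-negative integer matrix, features x samples. Row names
#'   are taken as feature ids and column names as sample ids unless
#'   `feature_ids` / `sample_ids` are given.
#' @param feature_ids Character vector of unique feature ids.
#' @param sample_ids Character vector of unique sample ids.
#' @param taxonomy Optional character vector of lineage strings, one per
#'   feature (e.g. `"Bacteria;Firmicutes;Clostridia"`), or `NULL`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix with dimnames), and `taxonomy`.
#' @export
count_table <- function(counts, feature_ids = rownames(counts),
                        sample_ids = colnames(counts), taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(feature_ids)) feature_ids <- sprintf("F%d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(counts)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(counts) != length(feature_ids) || ncol(counts) != length(sample_ids)) {
    stop_coab("count_table: dimensions of counts do not match id lists",
              class = "coabnet_validation_error")
  }
  if (anyDuplicated(feature_ids)) {
    stop_coab("count_table: duplicated feature id(s): ",
              paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
              class = "coabnet_validation_error")
  }
  if (anyDuplicated(sample_ids)) {
    stop_coab("count_table: duplicated sample id(s): ",
              paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
              class = "coabnet_validation_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_coab("count_table: counts must be finite and non-negative",
              class = "coabnet_validation_error")
  }
  if (any(counts != round(counts))) {
    stop_coab("count_table: counts must be integers",
              class = "coabnet_validation_error")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(feature_ids, sample_ids)
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != length(feature_ids)) {
      stop_coab("count_table: taxonomy length must equal number of features",
                class = "coabnet_validation_error")
    }
    names(taxonomy) <- feature_ids
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d features x %d samples (total reads %.3g)\n",
              nrow(x$counts), ncol(x$counts), sum(as.numeric(x$counts))))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

feature_ids <- function(table) rownames(table$counts)
sample_ids <- function(table) colnames(table$counts)

#' Read a count table from TSV or BIOM-style JSON
#'
#' The TSV convention is features as rows: first column feature id, header
#' row of sample ids, optional final `taxonomy` column. `transpose = TRUE`
#' reads samples-as-rows tables. BIOM reading uses the biomformat package
#' (dense or sparse JSON).
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom-json"`.
#' @param transpose For TSV input, treat rows as samples instead of features.
#' @return A validated [count_table()].
#' @export
load_count_table <- function(path, format = c("tsv", "biom-json"),
                             transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_coab("load_count_table: file does not exist: ", path,
              class = "coabnet_io_error")
  }
  if (format == "tsv") {
    load_count_tsv(path, transpose)
  } else {
    load_count_biom(path)
  }
}

load_count_tsv <- function(path, transpose) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) {
    stop_coab("load_count_table: parse error at line 1: ",
              "expected a header row and at least one data row in ", path,
              class = "coabnet_parse_error")
  }
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop_coab("load_count_table: parse error in ", path, ": ",
                conditionMessage(e), class = "coabnet_parse_error")
    }
  )
  if (ncol(df) < 2L) {
    stop_coab("load_count_table: parse error at line 1: ",
              "need an id column plus at least one count column",
              class = "coabnet_parse_error")
  }
  ids <- as.character(df[[1L]])
  taxonomy <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- as.character(df[[ncol(df)]])
    df <- df[, -ncol(df), drop = FALSE]
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(apply(mat, 1L, function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop_coab("load_count_table: parse error at line ",
              if (length(bad)) bad[1L] + 1L else 2L,
              ": non-numeric count value", class = "coabnet_parse_error")
  }
  rownames(mat) <- ids
  if (transpose) {
    mat <- t(mat)
    taxonomy <- NULL
  }
  count_table(mat, taxonomy = taxonomy)
}

load_count_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop_coab("load_count_table: the biomformat package is required for ",
              "format = 'biom-json'", class = "coabnet_io_error")
  }
  b <- tryCatch(biomformat::read_biom(path), error = function(e) {
    stop_coab("load_count_table: parse error in ", path, ": ",
              conditionMessage(e), class = "coabnet_parse_error")
  })
  mat <- as(biomformat::biom_data(b), "matrix")
  count_table(mat)
}

#' Write a count table to TSV
#'
#' Inverse of [load_count_table()] for the TSV convention (features as
#' rows, first column `feature_id`, optional trailing `taxonomy` column).
#' @param table A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(feature_id = feature_ids(table), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- unname(table$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the study's sample-depth and feature-abundance filters
#'
#' Drops samples whose total read count is below `min_sample_depth` (the
#' water-control depth rule), features whose maximum count across retained
#' samples is below `min_max_count`, and features whose mean relative
#' abundance across retained samples is below `min_mean_rel_abund`
#' (`mode = "prevalence"` instead drops features present in fewer than that
#' fraction of samples). The three rules are iterated to a fixed point so
#' the operation is idempotent: removing low-count features lowers column
#' sums, which can expose further samples to the depth rule.
#'
#' @param table A [count_table()].
#' @param min_sample_depth Minimum column sum for a sample to be kept.
#' @param min_max_count Minimum per-feature maximum count.
#' @param min_mean_rel_abund Minimum mean relative abundance (fraction).
#' @param mode Interpretation of the abundance rule: mean relative
#'   `"abundance"` (default) or `"prevalence"` (fraction of samples with a
#'   nonzero count).
#' @return The filtered [count_table()]; feature and sample order preserved.
#' @export
filter_features <- function(table, min_sample_depth = 0L, min_max_count = 0L,
                            min_mean_rel_abund = 0,
                            mode = c("abundance", "prevalence")) {
  mode <- match.arg(mode)
  stopifnot(min_sample_depth >= 0, min_max_count >= 0, min_mean_rel_abund >= 0)
  counts <- table$counts
  repeat {
    keep_s <- colSums(counts) >= min_sample_depth
    cur <- counts[, keep_s, drop = FALSE]
    if (ncol(cur) == 0L) {
      stop_coab("filter_features: empty result (all samples removed)",
                class = "coabnet_empty_error")
    }
    keep_f <- apply(cur, 1L, max) >= min_max_count
    cur <- cur[keep_f, , drop = FALSE]
    if (nrow(cur) > 0L && min_mean_rel_abund > 0) {
      rel <- sweep(cur, 2L, colSums(cur), "/")
      rel[is.nan(rel)] <- 0
      crit <- if (mode == "abundance") rowMeans(rel) else rowMeans(cur > 0)
      cur <- cur[crit >= min_mean_rel_abund, , drop = FALSE]
    }
    if (nrow(cur) == 0L) {
      stop_coab("filter_features: empty result (all features removed)",
                class = "coabnet_empty_error")
    }
    if (identical(dim(cur), dim(counts))) break
    counts <- cur
  }
  tax <- if (is.null(table$taxonomy)) NULL else table$taxonomy[rownames(counts)]
  count_table(counts, taxonomy = tax)
}

#' Read a per-sample metadata table
#'
#' TSV keyed by `sample_id`, with categorical cohort columns (e.g. `site`,
#' `bmi_class`), `age`, and any continuous covariates (short-chain fatty
#' acid concentrations, insulin, HOMA-IR, ...).
#'
#' @param path Path to a TSV with a `sample_id` column.
#' @param levels Optional named list of allowed levels for categorical
#'   columns, e.g. `list(bmi_class = c("lean", "obese"))`; values outside
#'   the declared set raise a validation error.
#' @return A `data.frame`, one row per sample.
#' @export
read_sample_metadata <- function(path, levels = list(bmi_class = c("lean", "obese"))) {
  if (!file.exists(path)) {
    stop_coab("read_sample_metadata: file does not exist: ", path,
              class = "coabnet_io_error")
  }
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_metadata(df, levels)
}

validate_metadata <- function(df, levels = list()) {
  if (!"sample_id" %in% names(df)) {
    stop_coab("metadata: missing required column 'sample_id'",
              class = "coabnet_validation_error")
  }
  if (anyDuplicated(df$sample_id)) {
    stop_coab("metadata: duplicated sample_id(s)",
              class = "coabnet_validation_error")
  }
  for (col in names(levels)) {
    if (col %in% names(df)) {
      bad <- setdiff(unique(df[[col]]), levels[[col]])
      if (length(bad)) {
        stop_coab("metadata: column '", col, "' has undeclared level(s): ",
                  paste(bad, collapse = ", "),
                  class = "coabnet_validation_error")
      }
      df[[col]] <- factor(df[[col]], levels = levels[[col]])
    }
  }
  df
}
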
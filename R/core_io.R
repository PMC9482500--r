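# Expression containers and two-channel spot-table I/O.
#
# Conventions fixed package-wide: genes in rows, samples in columns; labels are
# 0 = normal, 1 = tumor; missing values are encoded as empty fields or "NA" in
# the delimited formats.

REQUIRED_TWO_CHANNEL_COLS <- c(
  "spot_id", "gene_id", "sample_id",
  "CH1_MEAN", "CH1_MEDIAN", "CH2_MEAN", "CH2_MEDIAN", "CH1_BG", "CH2_BG"
)

#' Construct an expression matrix
#'
#' The central container of the package: a genes x samples real matrix of
#' (log-ratio) expression values with unique gene and sample identifiers,
#' optional binary class labels per sample, and a logical mask of missing
#' cells. Missing cells are stored as `NA` in `values` and flagged in
#' `missing_mask`.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Dimnames
#'   are used as identifiers when `gene_ids`/`sample_ids` are not given.
#' @param gene_ids,sample_ids character identifier vectors; must be unique.
#' @param labels optional per-sample class labels, coded 0 (normal) / 1
#'   (tumor), or a character vector with values `"normal"`/`"tumor"`.
#' @return an object of class `expr_matrix` with fields `values`, `gene_ids`,
#'   `sample_ids`, `labels` (integer or `NULL`) and `missing_mask`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values), labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop_ibosvm("identifier lengths do not match matrix dimensions",
                class = "ibosvm_shape_error")
  if (anyDuplicated(gene_ids))
    stop_ibosvm("duplicate gene_id: %s",
                paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
                class = "ibosvm_format_error")
  if (anyDuplicated(sample_ids))
    stop_ibosvm("duplicate sample_id: %s",
                paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
                class = "ibosvm_format_error")
  if (!is.null(labels)) {
    labels <- parse_labels(labels)
    if (length(labels) != ncol(values))
      stop_ibosvm("labels length (%d) != number of samples (%d)",
                  length(labels), ncol(values), class = "ibosvm_shape_error")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels, missing_mask = is.na(values)),
    class = "expr_matrix"
  )
}

parse_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    ok <- labels %in% c("normal", "tumor", "0", "1")
    if (!all(ok))
      stop_ibosvm("unrecognized label value: %s",
                  paste(unique(labels[!ok]), collapse = ", "),
                  class = "ibosvm_format_error")
    labels <- ifelse(labels %in% c("tumor", "1"), 1L, 0L)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop_ibosvm("labels must be binary 0/1", class = "ibosvm_format_error")
  labels
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d normal, %d tumor\n",
                sum(x$labels == 0L), sum(x$labels == 1L)))
  n_miss <- sum(x$missing_mask)
  if (n_miss > 0)
    cat(sprintf("  missing cells: %d (%.2f%%)\n",
                n_miss, 100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression table from delimited text
#'
#' Two formats are supported. `matrix_tsv` is a plain genes x samples matrix:
#' first column `gene_id`, header row of sample identifiers, and an optional
#' second header row whose first field is `label` giving per-sample classes.
#' `two_channel_tsv` is a long-format two-channel spot table with the named
#' columns `spot_id`, `gene_id`, `sample_id`, `CH1_MEAN`, `CH1_MEDIAN`,
#' `CH2_MEAN`, `CH2_MEDIAN`, `CH1_BG`, `CH2_BG`, an optional `label` column
#' and free extra feature columns. Empty fields and `NA` are missing values.
#'
#' @param path path to a tab-delimited text file.
#' @param format `"matrix_tsv"` or `"two_channel_tsv"`.
#' @return an [expression_matrix()] for `matrix_tsv`; a `data.frame` of class
#'   `two_channel_table` for `two_channel_tsv`.
#' @export
read_expression_table <- function(path, format = c("matrix_tsv", "two_channel_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_ibosvm("file not found: %s", path, class = "ibosvm_io_error")
  switch(format,
         matrix_tsv = read_matrix_tsv(path),
         two_channel_tsv = read_two_channel_tsv(path))
}

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2)
    stop_ibosvm("matrix_tsv needs a header and at least one gene row",
                class = "ibosvm_format_error")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  labels <- NULL
  body_start <- 2L
  second <- strsplit(lines[[2]], "\t", fixed = TRUE)[[1]]
  if (identical(second[[1]], "label")) {
    labels <- second[-1]
    body_start <- 3L
  }
  body <- strsplit(lines[seq(body_start, length(lines))], "\t", fixed = TRUE)
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  values <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    length(cells) <- length(sample_ids)
    cells[!nzchar(cells) | is.na(cells)] <- NA_character_
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !is.na(cells) & cells != "NA")
    if (length(bad))
      stop_ibosvm("non-numeric value '%s' at gene %s, sample %s",
                  cells[bad[1]], gene_ids[i], sample_ids[bad[1]],
                  class = "ibosvm_parse_error")
    values[i, ] <- num
  }
  expression_matrix(values, gene_ids, sample_ids, labels)
}

read_two_channel_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                          colClasses = NA, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_TWO_CHANNEL_COLS, names(df))
  if (length(missing_cols))
    stop_ibosvm("two_channel_tsv missing required column(s): %s",
                paste(missing_cols, collapse = ", "),
                class = "ibosvm_format_error")
  intensity_cols <- setdiff(names(df), c("spot_id", "gene_id", "sample_id", "label"))
  for (col in intensity_cols) {
    if (!is.numeric(df[[col]])) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(num) & !is.na(df[[col]]))
      if (length(bad))
        stop_ibosvm("non-numeric value '%s' in column %s, row %d",
                    df[[col]][bad[1]], col, bad[1], class = "ibosvm_parse_error")
      df[[col]] <- num
    }
  }
  attr(df, "feature_columns") <- intensity_cols
  dup <- duplicated(df[, c("gene_id", "sample_id")])
  if (any(dup))
    stop_ibosvm("duplicate spot for gene %s in sample %s",
                df$gene_id[dup][1], df$sample_id[dup][1],
                class = "ibosvm_format_error")
  class(df) <- c("two_channel_table", "data.frame")
  df
}

#' Write an expression matrix to matrix_tsv
#'
#' Inverse of [read_expression_table()] for the `matrix_tsv` format; missing
#' cells are written as `NA`. Finite values round-trip exactly (full
#' double precision is written).
#'
#' @param x an `expr_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", x$sample_ids), collapse = "\t"), con)
  if (!is.null(x$labels))
    writeLines(paste(c("label", x$labels), collapse = "\t"), con)
  vals <- format(x$values, digits = 17, trim = TRUE, scientific = FALSE)
  vals[is.na(x$values)] <- "NA"
  writeLines(paste(x$gene_ids, apply(vals, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Log-ratio normalize a two-channel spot table
#'
#' Computes per spot `log2(CH1 / CH2)` from the chosen channel summary
#' (median by default, the usual choice for spot intensities) and
#' median-centers each sample so the per-array median log-ratio is exactly
#' zero. No background correction is applied unless requested; when
#' `background_subtract = TRUE` the per-channel background is subtracted and
#' the result floored at `bg_floor` to keep ratios defined.
#'
#' @param t a `two_channel_table`.
#' @param summary `"median"` or `"mean"`: which per-spot intensity summary
#'   feeds the ratio.
#' @param background_subtract subtract `CHx_BG` from the channel summaries.
#' @param bg_floor positive floor applied after background subtraction.
#' @return an [expression_matrix()] of centered log2 ratios, with labels when
#'   the table carries a `label` column.
#' @export
log_ratio_normalize <- function(t, summary = c("median", "mean"),
                                background_subtract = FALSE, bg_floor = 1e-3) {
  stopifnot(inherits(t, "two_channel_table"))
  summary <- match.arg(summary)
  suffix <- toupper(summary)
  ch1 <- t[[paste0("CH1_", suffix)]]
  ch2 <- t[[paste0("CH2_", suffix)]]
  if (background_subtract) {
    ch1 <- pmax(ch1 - t$CH1_BG, bg_floor)
    ch2 <- pmax(ch2 - t$CH2_BG, bg_floor)
  }
  bad <- which(!is.na(ch1) & !is.na(ch2) & (ch1 <= 0 | ch2 <= 0))
  if (length(bad))
    stop_ibosvm("non-positive intensity at spot %s (sample %s)",
                t$spot_id[bad[1]], t$sample_id[bad[1]],
                class = "ibosvm_value_error")
  ratio <- log2(ch1 / ch2)

  gene_ids <- unique(t$gene_id)
  sample_ids <- unique(t$sample_id)
  values <- matrix(NA_real_, length(gene_ids), length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  values[cbind(match(t$gene_id, gene_ids), match(t$sample_id, sample_ids))] <- ratio

  medians <- apply(values, 2, stats::median, na.rm = TRUE)
  all_missing <- is.na(medians)
  if (any(all_missing))
    stop_ibosvm("sample %s has no observed intensities",
                sample_ids[which(all_missing)[1]], class = "ibosvm_value_error")
  values <- sweep(values, 2, medians)

  labels <- NULL
  if ("label" %in% names(t))
    labels <- t$label[match(sample_ids, t$sample_id)]
  expression_matrix(values, gene_ids, sample_ids, labels)
}

#' Impute missing expression values by group means
#'
#' Each missing cell is replaced by the mean of the gene's observed values
#' over samples sharing the same class label; when labels are absent (or a
#' label group has no observed value for that gene) the mean over all
#' observed samples is used. Observed cells are unchanged, so the operation
#' is idempotent.
#'
#' @param x an `expr_matrix`.
#' @return an `expr_matrix` with no missing values (`missing_mask` all false).
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  values <- x$values
  obs_per_gene <- rowSums(!is.na(values))
  if (any(obs_per_gene == 0))
    stop_ibosvm("gene %s has no observed values",
                x$gene_ids[which(obs_per_gene == 0)[1]],
                class = "ibosvm_value_error")
  if (!any(is.na(values))) return(x)

  gene_mean <- rowMeans(values, na.rm = TRUE)
  groups <- if (is.null(x$labels)) rep(0L, ncol(values)) else x$labels
  for (g in unique(groups)) {
    cols <- groups == g
    block <- values[, cols, drop = FALSE]
    grp_mean <- rowMeans(block, na.rm = TRUE)
    grp_mean[is.nan(grp_mean)] <- gene_mean[is.nan(grp_mean)]
    miss <- is.na(block)
    block[miss] <- grp_mean[row(block)[miss]]
    values[, cols] <- block
  }
  expression_matrix(values, x$gene_ids, x$sample_ids, x$labels)
}
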
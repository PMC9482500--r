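# Synthetic two-channel microarray data with known ground truth: planted
# differentially expressed genes, block-correlated gene modules, and missing
# values. Every pipeline stage is testable against the generator's truth
# without any external download.

#' Generate a synthetic expression dataset with planted structure
#'
#' Produces a genes x samples log-ratio matrix. Genes inside a correlation
#' block share a per-sample latent factor:
#' `value = sqrt(rho) * factor + sqrt(1 - rho) * noise`, which gives
#' within-block correlation `rho` in expectation. Informative genes get a
#' class-mean shift of `effect_size` added to tumor samples. Missing cells are planted uniformly at random at `missing_rate` (never
#' emptying a gene's label group entirely). Labels are balanced: the first
#' half of the samples is normal (0), the second half tumor (1).
#'
#' Defaults model a modest two-channel tumor/normal study: 200 genes, 60
#' arrays, 10 informative genes at 1.5-SD effect, four 25-gene correlation
#' blocks at rho 0.7, unit noise, 1% missing spots.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param n_informative number of planted differential genes; these are the
#'   last `n_informative` genes, outside the correlation blocks when room
#'   allows.
#' @param blocks either a list of gene-index vectors or a 2-vector
#'   `c(n_blocks, block_size)`; default 4 blocks of 25 genes.
#' @param rho within-block correlation, `0 <= rho < 1`.
#' @param effect_size class shift on informative genes, in log2-ratio units
#'   (residual-SD units when `noise_sd = 1`).
#' @param noise_sd residual SD of the log-ratios.
#' @param missing_rate expected fraction of missing cells.
#' @param seed integer seed; identical seed gives identical output.
#' @return list with `expr` (labeled [expression_matrix()]), `labels`, and
#'   `truth` (informative gene ids, effect size, block memberships,
#'   missing-value rate, noise SD, seed).
#' @export
generate_dataset <- function(n_genes = 200, n_samples = 60, n_informative = 10,
                             blocks = c(4, 25), rho = 0.7, effect_size = 1.5,
                             noise_sd = 1, missing_rate = 0.01, seed = 1) {
  if (n_informative > n_genes)
    stop_ibosvm("n_informative (%d) exceeds n_genes (%d)", n_informative,
                n_genes, class = "ibosvm_param_error")
  if (rho < 0 || rho >= 1)
    stop_ibosvm("rho must lie in [0, 1)", class = "ibosvm_param_error")
  set.seed(seed)

  if (!is.list(blocks)) {
    n_blocks <- blocks[1]
    block_size <- blocks[2]
    if (n_blocks * block_size > n_genes)
      stop_ibosvm("blocks cover more genes than exist", class = "ibosvm_param_error")
    blocks <- split(seq_len(n_blocks * block_size),
                    rep(seq_len(n_blocks), each = block_size))
  }
  if (anyDuplicated(unlist(blocks)))
    stop_ibosvm("correlation blocks must be disjoint", class = "ibosvm_param_error")

  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
  labels <- rep(c(0L, 1L), c(ceiling(n_samples / 2), floor(n_samples / 2)))

  values <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                   n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
  for (b in blocks) {
    factor_b <- stats::rnorm(n_samples, sd = noise_sd)
    values[b, ] <- sqrt(rho) * matrix(factor_b, length(b), n_samples,
                                      byrow = TRUE) +
      sqrt(1 - rho) * values[b, , drop = FALSE]
  }

  # informative genes: last n_informative indices (outside blocks when the
  # blocks only cover the front of the gene list)
  informative <- utils::tail(seq_len(n_genes), n_informative)
  values[informative, labels == 1L] <-
    values[informative, labels == 1L, drop = FALSE] + effect_size

  if (missing_rate > 0) {
    miss <- which(stats::runif(n_genes * n_samples) < missing_rate)
    values[miss] <- NA_real_
    # never empty a gene's label group: restore one cell where it happened
    for (g in seq_len(n_genes)) {
      for (cls in c(0L, 1L)) {
        cols <- which(labels == cls)
        if (all(is.na(values[g, cols]))) {
          values[g, cols[1]] <- stats::rnorm(1, sd = noise_sd)
        }
      }
    }
  }

  truth <- list(
    informative = gene_ids[informative],
    effect_size = effect_size,
    blocks = lapply(blocks, function(b) gene_ids[b]),
    rho = rho, noise_sd = noise_sd, missing_rate = missing_rate, seed = seed
  )
  expr <- expression_matrix(values, gene_ids, sample_ids, labels)
  list(expr = expr, labels = labels, truth = truth)
}

#' Convert an expression matrix to a two-channel spot table
#'
#' The inverse of [log_ratio_normalize()]: CH2 intensities are drawn around
#' `baseline_intensity` (log-normal multiplicative noise of SD `noise_sd` on
#' the log2 scale; exact at `noise_sd = 0`), and
#' `CH1 = CH2 * 2^value * 2^eps`. Mean and median summaries per channel
#' differ by a small deterministic factor, background columns sit at 1% of
#' baseline, and deterministic filler transforms pad the table to the full
#' 54-feature layout of archival two-channel scans (intensity means/medians,
#' backgrounds, sums of medians/means and their ratios, and derived
#' quantities).
#'
#' @param x an `expr_matrix` with finite values.
#' @param baseline_intensity positive CH2 center (default 1000).
#' @param noise_sd SD of multiplicative (log2-scale) noise; 0 = exact.
#' @param seed integer seed.
#' @return a `two_channel_table` with exactly 54 feature columns plus
#'   spot_id, gene_id, sample_id and (when labeled) label.
#' @export
to_two_channel <- function(x, baseline_intensity = 1000, noise_sd = 0,
                           seed = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (baseline_intensity <= 0)
    stop_ibosvm("baseline_intensity must be positive", class = "ibosvm_param_error")
  set.seed(seed)
  n_genes <- nrow(x$values)
  n_samples <- ncol(x$values)

  long <- expand.grid(gene = seq_len(n_genes), sample = seq_len(n_samples))
  value <- x$values[cbind(long$gene, long$sample)]
  n <- nrow(long)
  ch2 <- baseline_intensity * 2^(stats::rnorm(n, sd = noise_sd))
  ch1 <- ch2 * 2^(value + stats::rnorm(n, sd = noise_sd))

  df <- data.frame(
    spot_id = sprintf("spot_%06d", seq_len(n)),
    gene_id = x$gene_ids[long$gene],
    sample_id = x$sample_ids[long$sample],
    stringsAsFactors = FALSE
  )
  if (!is.null(x$labels)) df$label <- x$labels[long$sample]

  df$CH1_MEAN <- ch1 * 1.02        # mean slightly above median: skewed spots
  df$CH1_MEDIAN <- ch1
  df$CH2_MEAN <- ch2 * 1.02
  df$CH2_MEDIAN <- ch2
  df$CH1_BG <- rep(0.01 * baseline_intensity, n)
  df$CH2_BG <- rep(0.01 * baseline_intensity, n)

  # deterministic filler transforms up to the 54-feature layout
  fillers <- list(
    SUM_MEDIANS = df$CH1_MEDIAN + df$CH2_MEDIAN,
    SUM_MEANS = df$CH1_MEAN + df$CH2_MEAN,
    RAT_MEDIANS = df$CH1_MEDIAN / df$CH2_MEDIAN,
    RAT_MEANS = df$CH1_MEAN / df$CH2_MEAN,
    LOG_RAT_MEDIANS = log2(df$CH1_MEDIAN / df$CH2_MEDIAN),
    CH1_NET = df$CH1_MEDIAN - df$CH1_BG,
    CH2_NET = df$CH2_MEDIAN - df$CH2_BG
  )
  n_more <- 54 - 6 - length(fillers)
  for (j in seq_len(n_more))
    fillers[[sprintf("FEATURE_%02d", j)]] <-
      (df$CH1_MEDIAN + j) / (df$CH2_MEDIAN + j)
  for (nm in names(fillers)) df[[nm]] <- fillers[[nm]]

  # NA expression -> missing spot intensities
  miss <- is.na(value)
  intensity_cols <- setdiff(names(df), c("spot_id", "gene_id", "sample_id", "label"))
  for (col in intensity_cols) df[[col]][miss] <- NA_real_

  class(df) <- c("two_channel_table", "data.frame")
  df
}

#' Write a two-channel spot table as TSV
#'
#' @param t a `two_channel_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_two_channel <- function(t, path) {
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write ground truth metadata as JSON
#'
#' @param truth the `truth` element of [generate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
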
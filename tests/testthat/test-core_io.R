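test_that("matrix_tsv write/read round-trips values, ids, labels and mask", {
  sim <- generate_dataset(n_genes = 30, n_samples = 12, n_informative = 3,
                          blocks = c(1, 10), missing_rate = 0.05, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$expr, path)
  back <- read_expression_table(path, "matrix_tsv")
  expect_identical(back$gene_ids, sim$expr$gene_ids)
  expect_identical(back$sample_ids, sim$expr$sample_ids)
  expect_identical(back$labels, sim$expr$labels)
  expect_identical(back$missing_mask, sim$expr$missing_mask)
  expect_identical(back$values, sim$expr$values)
})

test_that("duplicate gene rows are rejected with the duplicate named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gX\t1\t2", "gX\t3\t4"), path)
  expect_error(read_expression_table(path, "matrix_tsv"), "gX")
})

test_that("non-numeric cells are reported with their location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\toops"), path)
  expect_error(read_expression_table(path, "matrix_tsv"), "oops")
})

test_that("two-channel reader recognizes the full 54-feature layout", {
  sim <- generate_dataset(n_genes = 8, n_samples = 4, n_informative = 2,
                          blocks = list(), missing_rate = 0, seed = 2)
  tab <- to_two_channel(impute_missing(sim$expr), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_two_channel(tab, path)
  back <- read_expression_table(path, "two_channel_tsv")
  expect_s3_class(back, "two_channel_table")
  expect_length(attr(back, "feature_columns"), 54)
  expect_true(all(c("CH1_MEDIAN", "CH2_BG") %in% attr(back, "feature_columns")))
})

test_that("two-channel reader names a missing required column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spot_id\tgene_id\tsample_id\tCH1_MEAN", "p1\tg1\ts1\t10"), path)
  expect_error(read_expression_table(path, "two_channel_tsv"), "CH2_MEDIAN")
})

test_that("log-ratio normalization centers each sample's median at zero", {
  # equal channels -> all zero after centering
  sim <- generate_dataset(n_genes = 10, n_samples = 5, n_informative = 0,
                          blocks = list(), missing_rate = 0, seed = 3)
  zero_expr <- expression_matrix(matrix(0, 10, 5,
                                        dimnames = dimnames(sim$expr$values)))
  tab <- to_two_channel(zero_expr, seed = 1)
  out <- log_ratio_normalize(tab)
  expect_equal(max(abs(out$values)), 0)

  # single sample with ratios {4, 1, 1}: raw log2 {2, 0, 0}, median 0
  tab1 <- data.frame(
    spot_id = c("p1", "p2", "p3"), gene_id = c("g1", "g2", "g3"),
    sample_id = "s1",
    CH1_MEAN = c(400, 100, 100), CH1_MEDIAN = c(400, 100, 100),
    CH2_MEAN = 100, CH2_MEDIAN = 100, CH1_BG = 1, CH2_BG = 1
  )
  class(tab1) <- c("two_channel_table", "data.frame")
  out1 <- log_ratio_normalize(tab1)
  expect_equal(unname(out1$values[, 1]), c(2, 0, 0))

  # planted 2-fold changes recovered as +/-1 within noise
  base <- matrix(rep(c(1, -1, 0, 0), 5), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  tab2 <- to_two_channel(expression_matrix(base), noise_sd = 0.02, seed = 9)
  out2 <- log_ratio_normalize(tab2)
  expect_equal(unname(out2$values[1, ] - out2$values[3, ]),
               rep(1, 5), tolerance = 0.15)
  expect_equal(unname(out2$values[2, ] - out2$values[3, ]),
               rep(-1, 5), tolerance = 0.15)
})

test_that("per-sample median is exactly zero after normalization", {
  sim <- generate_dataset(n_genes = 21, n_samples = 8, n_informative = 5,
                          blocks = c(1, 7), missing_rate = 0, seed = 4)
  tab <- to_two_channel(impute_missing(sim$expr), noise_sd = 0.1, seed = 4)
  out <- log_ratio_normalize(tab)
  expect_equal(unname(apply(out$values, 2, median)), rep(0, 8))
})

test_that("zero or negative intensity errors identify the spot", {
  tab <- data.frame(
    spot_id = c("p1", "p2"), gene_id = c("g1", "g2"), sample_id = "s1",
    CH1_MEAN = c(100, 0), CH1_MEDIAN = c(100, 0),
    CH2_MEAN = 100, CH2_MEDIAN = 100, CH1_BG = 1, CH2_BG = 1
  )
  class(tab) <- c("two_channel_table", "data.frame")
  expect_error(log_ratio_normalize(tab), "p2")
})

test_that("imputation fills with label-group means and is idempotent", {
  # unlabeled: gene observed {2, 4} -> imputed 3
  x <- expression_matrix(matrix(c(2, NA, 4), 1, 3,
                                dimnames = list("g1", c("s1", "s2", "s3"))))
  out <- impute_missing(x)
  expect_equal(unname(out$values[1, 2]), 3)
  expect_false(any(out$missing_mask))

  # labeled: imputed value equals the group mean, checked by brute force
  sim <- generate_dataset(n_genes = 40, n_samples = 16, n_informative = 4,
                          blocks = c(2, 10), missing_rate = 0.08, seed = 5)
  filled <- impute_missing(sim$expr)
  miss <- which(sim$expr$missing_mask, arr.ind = TRUE)
  for (r in seq_len(nrow(miss))) {
    g <- miss[r, 1]; s <- miss[r, 2]
    grp <- which(sim$labels == sim$labels[s])
    expected <- mean(sim$expr$values[g, grp], na.rm = TRUE)
    if (is.nan(expected)) expected <- mean(sim$expr$values[g, ], na.rm = TRUE)
    expect_equal(unname(filled$values[g, s]), expected)
  }
  # observed cells unchanged; idempotent
  obs <- !sim$expr$missing_mask
  expect_identical(filled$values[obs], sim$expr$values[obs])
  expect_identical(impute_missing(filled)$values, filled$values)
})

test_that("a gene with no observed values is an error naming the gene", {
  x <- expression_matrix(matrix(c(NA, NA, 1, 2), 2, 2, byrow = TRUE,
                                dimnames = list(c("gBad", "gOk"),
                                                c("s1", "s2"))))
  expect_error(impute_missing(x), "gBad")
})
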
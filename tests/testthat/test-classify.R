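test_that("SVM separates separable toy data and is deterministic", {
  X <- rbind(g1 = c(-2, -2.2, -1.8, 2, 2.1, 1.9),
             g2 = c(-1, -1.1, -0.9, 1, 1.2, 0.8))
  colnames(X) <- paste0("s", 1:6)
  y <- c(0, 0, 0, 1, 1, 1)
  clf <- train_svm(X, y, kernel = "linear", seed = 1)
  expect_equal(predict(clf, X), y)

  clf2 <- train_svm(X, y, kernel = "linear", seed = 1)
  expect_identical(predict(clf, X, type = "score"),
                   predict(clf2, X, type = "score"))
  # scores orient toward the tumor class
  expect_true(all(predict(clf, X, type = "score")[y == 1] >
                    predict(clf, X, type = "score")[y == 0]))
  expect_error(train_svm(X, rep(1, 6)), "class")
})

test_that("selected genes beat a label-permuted baseline out of sample", {
  gaps <- numeric(10)
  for (s in 1:10) {
    sim <- generate_dataset(n_genes = 50, n_samples = 60, n_informative = 8,
                            blocks = c(2, 10), effect_size = 2,
                            missing_rate = 0, seed = s)
    x <- sim$expr
    sel_genes <- sim$truth$informative
    train <- rep(c(TRUE, FALSE), length.out = 60)
    clf <- train_svm(x$values[sel_genes, train], x$labels[train], seed = s)
    acc <- mean(predict(clf, x$values[sel_genes, !train]) == x$labels[!train])
    set.seed(s)
    y_perm <- sample(x$labels[train])
    clf_perm <- tryCatch(
      train_svm(x$values[sel_genes, train], y_perm, seed = s),
      error = function(e) NULL)
    acc_perm <- if (is.null(clf_perm)) 0.5 else
      mean(predict(clf_perm, x$values[sel_genes, !train]) == x$labels[!train])
    gaps[s] <- acc - acc_perm
  }
  expect_gte(mean(gaps), 0.3)
})

test_that("confusion counts match a brute-force tally", {
  y <- c(1, 1, 0, 0, 1)
  expect_equal(unclass(confusion_counts(y, y))[c("fpv", "fnv")],
               list(fpv = 0L, fnv = 0L))
  cc_flip <- confusion_counts(y, 1 - y)
  expect_equal(cc_flip$tpv + cc_flip$tnv, 0L)

  set.seed(40)
  for (i in 1:5) {
    yt <- rbinom(30, 1, 0.5); yp <- rbinom(30, 1, 0.5)
    cc <- confusion_counts(yt, yp)
    tally <- c(tpv = 0, fpv = 0, fnv = 0, tnv = 0)
    for (j in 1:30) {
      key <- if (yt[j] == 1 && yp[j] == 1) "tpv"
      else if (yt[j] == 0 && yp[j] == 1) "fpv"
      else if (yt[j] == 1 && yp[j] == 0) "fnv"
      else "tnv"
      tally[key] <- tally[key] + 1
    }
    expect_equal(unlist(unclass(cc)[names(tally)]), tally)
    expect_equal(sum(unlist(unclass(cc)[1:4])), 30)
  }
  expect_error(confusion_counts(c(0, 1), c(0)), "length")
})

test_that("metric formulas and bounds hold on random confusion counts", {
  cc <- structure(list(tpv = 9L, fpv = 1L, fnv = 1L, tnv = 9L),
                  class = "confusion_counts")
  rep <- metrics_report(cc)
  expect_equal(rep$precision, 0.9)
  expect_equal(rep$recall, 0.9)
  expect_equal(rep$f_measure, 0.9)
  expect_equal(rep$specificity, 0.9)
  expect_equal(rep$accuracy, 0.9)

  set.seed(41)
  for (i in 1:20) {
    counts <- as.list(rpois(4, 5) + 1L)
    names(counts) <- c("tpv", "fpv", "fnv", "tnv")
    r <- metrics_report(structure(counts, class = "confusion_counts"))
    expect_equal(r$precision, counts$tpv / (counts$tpv + counts$fpv))
    expect_equal(r$recall, counts$tpv / (counts$tpv + counts$fnv))
    expect_equal(r$specificity, counts$tnv / (counts$tnv + counts$fpv))
    expect_equal(r$accuracy,
                 (counts$tpv + counts$tnv) / sum(unlist(counts)))
    for (m in c("precision", "recall", "f_measure", "specificity", "accuracy"))
      expect_true(r[[m]] >= 0 && r[[m]] <= 1)
    # harmonic mean lies between precision and recall
    expect_gte(r$f_measure, min(r$precision, r$recall) - 1e-12)
    expect_lte(r$f_measure, max(r$precision, r$recall) + 1e-12)
  }

  # zero denominators flag, not silently zero
  none_pred <- metrics_report(confusion_counts(c(1, 0), c(0, 0)))
  expect_true(is.na(none_pred$precision))
  expect_true("precision" %in% none_pred$undefined)
  perfect_prec <- metrics_report(confusion_counts(c(1, 1, 0), c(1, 0, 0)))
  expect_equal(perfect_prec$precision, 1)
})

test_that("ROC table matches brute-force counting and is monotone", {
  set.seed(42)
  y <- rep(c(0, 1), 15)
  scores <- rnorm(30) + y
  roc <- roc_table(scores, y)
  expect_equal(roc$TPR[roc$threshold == -Inf], 1)
  expect_equal(roc$FPR[roc$threshold == -Inf], 1)
  expect_equal(roc$TPR[roc$threshold == max(scores)], 0)

  for (r in seq_len(nrow(roc))) {
    t <- roc$threshold[r]
    expect_equal(roc$TPR[r], sum(scores > t & y == 1) / sum(y == 1))
    expect_equal(roc$FPR[r], sum(scores > t & y == 0) / sum(y == 0))
  }
  o <- order(roc$threshold)
  expect_true(all(diff(roc$TPR[o]) <= 0))
  expect_true(all(diff(roc$FPR[o]) <= 0))

  # perfectly separating scores contain the (0, 1) corner
  roc_sep <- roc_table(y * 2 - 1, y)
  expect_true(any(roc_sep$FPR == 0 & roc_sep$TPR == 1))
  expect_error(roc_table(scores, rep(1, 30)), "classes")
})

test_that("mean TPR and AUC summarize ROC points", {
  pts <- data.frame(FPR = c(0, 0.5, 1), TPR = c(1, 1, 1))
  expect_equal(mean_tpr(pts), 1)
  expect_equal(roc_auc(pts), 1)
  expect_error(mean_tpr(numeric(0)), "point")
})

test_that("report comparison is antisymmetric and exact on benchmarks", {
  reports <- benchmark_reports("IBO_SVM")
  cmp <- compare_reports(reports)
  dca <- cmp[cmp$other == "DCA", ]
  expect_equal(dca$precision, 1.84)
  expect_equal(dca$accuracy, 8.06)

  rev_cmp <- compare_reports(benchmark_reports("DCA")[c("DCA", "IBO_SVM")])
  expect_equal(rev_cmp$precision, -1.84)

  self_cmp <- compare_reports(list(a = reports[[1]], b = reports[[1]]))
  expect_true(all(unlist(self_cmp[, -(1:2)]) == 0))
})

test_that("stratified cross-validation keeps folds balanced and honest", {
  sim <- generate_dataset(n_genes = 40, n_samples = 40, n_informative = 6,
                          blocks = c(2, 10), effect_size = 2,
                          missing_rate = 0, seed = 50)
  x <- sim$expr
  rep <- cross_validate(x, x$labels, folds = 5, seed = 1, select_k = 6,
                        n_bats = 10, n_iter = 25)
  # fold sizes differ by at most 1 within each class
  for (cls in 0:1) {
    sizes <- table(rep$fold_assignment[x$labels == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # planted signal: well above chance
  expect_gt(rep$accuracy, 0.7)

  # noise-only data stays near chance
  sim0 <- generate_dataset(n_genes = 40, n_samples = 40, n_informative = 0,
                           blocks = list(), missing_rate = 0, seed = 51)
  accs <- sapply(1:5, function(s)
    cross_validate(sim0$expr, sim0$labels, folds = 4, seed = s, select_k = 5,
                   n_bats = 8, n_iter = 10)$accuracy)
  expect_gte(mean(accs), 0.25)
  expect_lte(mean(accs), 0.75)
  expect_error(cross_validate(x, x$labels, folds = 1), "folds")
})
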
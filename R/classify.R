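# SVM classification on selected genes and the full evaluation battery:
# confusion counts, precision/recall/F-measure/specificity/accuracy, ROC
# operating points, mean TPR, pairwise method comparison, and stratified
# nested cross-validation. The positive class is tumor (label 1).

#' Train a binary SVM on selected genes
#'
#' Fits a support-vector machine on the (selected-gene) expression of each
#' sample. The solver is e1071/libsvm; the contract here is the interface:
#' a fitted classifier exposing predicted labels and decision scores,
#' deterministic given the inputs.
#'
#' @param X_selected genes x samples matrix restricted to the selected genes.
#' @param y binary labels (0/1), one per sample, both classes present.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C soft-margin cost (default 1).
#' @param seed integer seed (kept for interface symmetry; the fit itself is
#'   deterministic).
#' @return an `svm_classifier` with a [predict()] method returning labels and,
#'   with `type = "score"`, decision values oriented so larger means tumor.
#' @export
train_svm <- function(X_selected, y, kernel = c("rbf", "linear"), C = 1,
                      seed = 1) {
  kernel <- match.arg(kernel)
  X_selected <- as_values(X_selected)
  y <- parse_labels(y)
  if (length(unique(y)) < 2)
    stop_ibosvm("training labels contain a single class", class = "ibosvm_value_error")
  if (min(table(y)) < 2)
    stop_ibosvm("need at least 2 samples per class", class = "ibosvm_value_error")
  if (!is.null(seed)) set.seed(seed)
  fit <- e1071::svm(
    x = t(X_selected), y = factor(y, levels = c(0, 1)),
    kernel = if (kernel == "rbf") "radial" else "linear",
    cost = C, scale = FALSE
  )
  structure(list(fit = fit, kernel = kernel, C = C,
                 gene_ids = rownames(X_selected)),
            class = "svm_classifier")
}

#' @param object an `svm_classifier`.
#' @param newdata genes x samples matrix (same genes as at training).
#' @param type `"label"` for 0/1 predictions, `"score"` for decision values.
#' @param ... unused.
#' @rdname train_svm
#' @export
predict.svm_classifier <- function(object, newdata, type = c("label", "score"),
                                   ...) {
  type <- match.arg(type)
  newdata <- as_values(newdata)
  pred <- stats::predict(object$fit, t(newdata), decision.values = TRUE)
  if (type == "label") return(as.integer(as.character(pred)))
  dv <- drop(attr(pred, "decision.values"))
  # libsvm orients the decision value toward the first training class; flip
  # so that larger score always means the positive (tumor) class
  if (grepl("^0/1", colnames(attr(pred, "decision.values"))[1])) -dv else dv
}

#' Confusion counts for binary predictions
#'
#' Standard 2x2 tally with tumor (1) as the positive class: `tpv` true
#' positives, `fpv` false positives, `fnv` false negatives, `tnv` true
#' negatives.
#'
#' @param y_true,y_pred binary label vectors of equal length.
#' @return a `confusion_counts` list (tpv, fpv, fnv, tnv).
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_ibosvm("y_true and y_pred lengths differ (%d vs %d)",
                length(y_true), length(y_pred), class = "ibosvm_shape_error")
  y_true <- parse_labels(y_true)
  y_pred <- parse_labels(y_pred)
  structure(list(
    tpv = sum(y_true == 1 & y_pred == 1),
    fpv = sum(y_true == 0 & y_pred == 1),
    fnv = sum(y_true == 1 & y_pred == 0),
    tnv = sum(y_true == 0 & y_pred == 0)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Precision `tpv/(tpv+fpv)`, recall (sensitivity, the true-positive rate)
#' `tpv/(tpv+fnv)`, F-measure `2*Pr*Re/(Pr+Re)`, specificity `tnv/(tnv+fpv)`
#' and accuracy `(tpv+tnv)/total`. A metric whose denominator is zero is
#' returned as `NA` and named in the `undefined` field rather than silently
#' reported as 0.
#'
#' @param c a `confusion_counts`.
#' @return a `classification_report` list of proportions plus `counts` and
#'   `undefined`.
#' @export
metrics_report <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(c$tpv, c$tpv + c$fpv)
  recall <- safe_div(c$tpv, c$tpv + c$fnv)
  f_measure <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  specificity <- safe_div(c$tnv, c$tnv + c$fpv)
  total <- c$tpv + c$fpv + c$fnv + c$tnv
  accuracy <- safe_div(c$tpv + c$tnv, total)
  metrics <- list(precision = precision, recall = recall,
                  f_measure = f_measure, specificity = specificity,
                  accuracy = accuracy)
  undefined <- names(metrics)[vapply(metrics, is.na, logical(1))]
  structure(c(metrics, list(counts = c, undefined = undefined)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification_report (% of evaluated samples):\n")
  for (m in c("precision", "recall", "f_measure", "specificity", "accuracy"))
    cat(sprintf("  %-12s %s\n", m,
                if (is.na(x[[m]])) "undefined" else sprintf("%.2f", 100 * x[[m]])))
  invisible(x)
}

#' ROC operating points over a threshold grid
#'
#' For each threshold t, predicts tumor when `score > t` and tabulates the
#' false-positive and true-positive rates. With the default grid (`-Inf` plus
#' every observed score) the points sweep from (1, 1) down to (0, 0).
#'
#' @param scores real-valued decision scores, larger = more tumor-like.
#' @param y_true binary labels containing both classes.
#' @param thresholds threshold grid; default `-Inf` and the sorted unique
#'   scores.
#' @return data.frame (threshold, FPR, TPR) sorted by FPR then TPR.
#' @export
roc_table <- function(scores, y_true, thresholds = NULL) {
  y_true <- parse_labels(y_true)
  if (length(unique(y_true)) < 2)
    stop_ibosvm("ROC requires both classes in y_true", class = "ibosvm_value_error")
  thresholds <- thresholds %||% c(-Inf, sort(unique(scores)))
  pos <- sum(y_true == 1)
  neg <- sum(y_true == 0)
  tpr <- vapply(thresholds, function(t) sum(scores > t & y_true == 1) / pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores > t & y_true == 0) / neg,
                numeric(1))
  df <- data.frame(threshold = thresholds, FPR = fpr, TPR = tpr)
  df[order(df$FPR, df$TPR), , drop = FALSE]
}

#' Mean true-positive rate of tabulated ROC points
#'
#' The arithmetic mean of the TPR column — the "average value of the ROC
#' curve" summary used alongside trapezoidal AUC for comparing classifiers
#' across a common set of operating points. Reported as a percentage it is
#' rounded to one decimal.
#'
#' @param roc_points data.frame with a `TPR` column, or a numeric TPR vector.
#' @return mean TPR as a proportion.
#' @export
mean_tpr <- function(roc_points) {
  tpr <- if (is.data.frame(roc_points)) roc_points$TPR else as.numeric(roc_points)
  if (length(tpr) == 0)
    stop_ibosvm("no ROC points given", class = "ibosvm_value_error")
  mean(tpr)
}

#' Trapezoidal area under the ROC curve
#'
#' @param roc_points data.frame with FPR and TPR columns.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(roc_points) {
  o <- order(roc_points$FPR, roc_points$TPR)
  x <- roc_points$FPR[o]; y <- roc_points$TPR[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Pairwise metric differences between classification reports
#'
#' Differences (reference minus other) in percentage points, rounded to two
#' decimals — the arithmetic used when one method's precision of 91.59% is
#' reported as "+1.84" over a competitor's 89.75%.
#'
#' @param reports named list of `classification_report`s (or plain named
#'   lists of proportions); the first entry is the reference.
#' @return data.frame: one row per non-reference method, one column per
#'   metric, values in percentage points.
#' @export
compare_reports <- function(reports) {
  if (length(reports) < 2)
    stop_ibosvm("need at least two reports to compare", class = "ibosvm_param_error")
  metrics <- c("precision", "recall", "f_measure", "specificity", "accuracy")
  ref <- reports[[1]]
  others <- reports[-1]
  rows <- lapply(names(others), function(nm) {
    diffs <- vapply(metrics, function(m)
      round(100 * (ref[[m]] - others[[nm]][[m]]), 2), numeric(1))
    as.data.frame(as.list(diffs))
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(reference = names(reports)[1], other = names(others),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Stratified nested cross-validation of selection + SVM
#'
#' Splits the samples into stratified folds (fold sizes differ by at most one
#' per class). Within each training fold, gene selection is performed from
#' scratch ([ibo_select()] by default) and an SVM is trained on the selected
#' genes only — the held-out fold never informs selection. Confusion counts
#' are pooled over folds into a single report; held-out decision scores are
#' kept for ROC analysis.
#'
#' @param X genes x samples matrix or `expr_matrix`.
#' @param y binary labels.
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling fold assignment and selection.
#' @param select_k genes to select per fold; `NULL` disables selection (all
#'   genes are used).
#' @param n_bats,n_iter optimizer size per fold.
#' @param kernel,C SVM parameters.
#' @param label_kernel,gene_kernel HSIC kernels for selection.
#' @return a `classification_report` with extra fields `roc` (ROC table from
#'   pooled held-out scores), `auc`, `mean_tpr`, `fold_assignment`, and
#'   `selected_per_fold`.
#' @export
cross_validate <- function(X, y, folds = 5, seed = 1, select_k = 10,
                           n_bats = 30, n_iter = 100,
                           kernel = "rbf", C = 1,
                           label_kernel = "delta", gene_kernel = "linear") {
  Xv <- as_values(X)
  y <- parse_labels(y)
  if (folds < 2)
    stop_ibosvm("folds must be >= 2", class = "ibosvm_param_error")
  if (min(table(y)) < folds)
    stop_ibosvm("cannot stratify: smallest class has %d samples for %d folds",
                min(table(y)), folds, class = "ibosvm_param_error")
  if (!is.null(seed)) set.seed(seed)
  fold_of <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  y_pred <- integer(length(y))
  scores <- numeric(length(y))
  selected_per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- fold_of != f
    X_tr <- Xv[, train, drop = FALSE]
    y_tr <- y[train]
    if (!is.null(select_k)) {
      sel <- ibo_select(X_tr, y_tr, k = min(select_k, nrow(X_tr)),
                        n_bats = n_bats, n_iter = n_iter, seed = NULL,
                        label_kernel = label_kernel, gene_kernel = gene_kernel)
      genes <- sel$mask
      selected_per_fold[[f]] <- sel$gene_ids
    } else {
      genes <- rep(TRUE, nrow(Xv))
      selected_per_fold[[f]] <- rownames(Xv)
    }
    clf <- train_svm(X_tr[genes, , drop = FALSE], y_tr, kernel = kernel, C = C,
                     seed = NULL)
    X_te <- Xv[genes, !train, drop = FALSE]
    y_pred[!train] <- predict(clf, X_te, type = "label")
    scores[!train] <- predict(clf, X_te, type = "score")
  }

  report <- metrics_report(confusion_counts(y, y_pred))
  report$roc <- roc_table(scores, y)
  report$auc <- roc_auc(report$roc)
  report$mean_tpr <- mean_tpr(report$roc)
  report$fold_assignment <- fold_of
  report$selected_per_fold <- selected_per_fold
  report
}
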
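# Published benchmark values shipped with the package: ROC operating points
# (FPR vs TPR per method) and the headline performance table for the
# DCA / DCN / IBO-SVM comparison arithmetic.

#' Benchmark ROC operating points
#'
#' Tabulated true-positive rates at five false-positive-rate operating points
#' for the DCA, DCN and IBO-SVM classifiers, as shipped in
#' `extdata/roc_operating_points.tsv`. Feeding one method's TPR column to
#' [mean_tpr()] gives that method's mean-TPR summary.
#'
#' @return data.frame with columns FPR, DCA, DCN, IBO_SVM.
#' @export
benchmark_roc_points <- function() {
  utils::read.delim(system.file("extdata", "roc_operating_points.tsv",
                                package = "ibosvm"))
}

#' Benchmark performance table
#'
#' Headline percentage metrics (precision, recall, F-measure, specificity,
#' accuracy) for DCA, DCN and IBO-SVM, as shipped in
#' `extdata/method_performance.tsv`. Rows can be passed to
#' [compare_reports()] (after scaling to proportions) to compute pairwise
#' percentage-point differences.
#'
#' @return data.frame with a `method` column and one column per metric.
#' @export
benchmark_performance <- function() {
  utils::read.delim(system.file("extdata", "method_performance.tsv",
                                package = "ibosvm"))
}

#' Benchmark table rows as comparable reports
#'
#' Converts [benchmark_performance()] into the named list of
#' proportion-scale reports that [compare_reports()] consumes, with the
#' chosen reference method first.
#'
#' @param reference method name to put first (default `"IBO_SVM"`).
#' @return named list of metric lists on the proportion scale.
#' @export
benchmark_reports <- function(reference = "IBO_SVM") {
  perf <- benchmark_performance()
  metrics <- c("precision", "recall", "f_measure", "specificity", "accuracy")
  reports <- lapply(seq_len(nrow(perf)), function(i)
    as.list(unlist(perf[i, metrics]) / 100))
  names(reports) <- perf$method
  c(reports[reference], reports[setdiff(names(reports), reference)])
}
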
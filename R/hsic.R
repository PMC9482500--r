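# Empirical Hilbert-Schmidt independence criterion between a sample-level
# gene kernel and a label kernel. The estimator is tr(HKHB) / (n-1)^2 with
# H = I - (1/n) 11' the centering matrix; the normalization keeps the value
# from growing with sample count and cancels when subsets are compared at
# fixed n.

center_kernel <- function(K) {
  rm_ <- rowMeans(K)
  K - outer(rm_, rep(1, ncol(K))) - outer(rep(1, nrow(K)), colMeans(K)) + mean(K)
}

#' Empirical HSIC between two kernel matrices
#'
#' Computes `tr(HKHB) / (n-1)^2`. For positive semidefinite inputs the value
#' is non-negative (up to numerical noise); it is zero when either kernel is
#' constant, since centering annihilates constants.
#'
#' @param K,B symmetric n x n kernel matrices over the same samples.
#' @return scalar HSIC estimate.
#' @export
empirical_hsic <- function(K, B) {
  if (!is.matrix(K) || !is.matrix(B) || any(dim(K) != dim(B)) ||
      nrow(K) != ncol(K))
    stop_ibosvm("K and B must be square matrices of the same size",
                class = "ibosvm_shape_error")
  n <- nrow(K)
  Kc <- center_kernel(K)
  sum(Kc * B) / (n - 1)^2      # tr(Kc B) = sum(Kc * B') ; B symmetric
}

#' HSIC of a weighted gene projection
#'
#' Forms the linear kernel of the u-weighted gene projection,
#' `K = (X'u)(X'u)'`, and evaluates [empirical_hsic()] against the label
#' kernel. Scaling `u` by `c` scales the value by `c^2`, so selection masks
#' are used at unit norm.
#'
#' @param X genes x samples matrix.
#' @param u gene weight vector (non-zero).
#' @param B label kernel matrix.
#' @return scalar HSIC value.
#' @export
projection_hsic <- function(X, u, B) {
  X <- as_values(X)
  if (length(u) != nrow(X))
    stop_ibosvm("u must have one weight per gene", class = "ibosvm_shape_error")
  if (all(u == 0))
    stop_ibosvm("u must be non-zero", class = "ibosvm_value_error")
  z <- drop(crossprod(X, u))
  K <- tcrossprod(z)
  empirical_hsic(K, B)
}

#' Build a label kernel
#'
#' @param y binary labels (0/1).
#' @param kind `"delta"` (`B_ij = 1` iff `y_i = y_j`, default) or `"linear"`
#'   (`B = y y'`).
#' @return n x n kernel matrix.
#' @export
label_kernel <- function(y, kind = c("delta", "linear")) {
  kind <- match.arg(kind)
  y <- as.numeric(y)
  switch(kind,
         delta = 1 * outer(y, y, `==`),
         linear = tcrossprod(y))
}

gene_kernel_matrix <- function(Xs, kind = c("linear", "rbf_median")) {
  kind <- match.arg(kind)
  if (kind == "linear") return(crossprod(Xs))  # samples x samples
  d2 <- as.matrix(stats::dist(t(Xs)))^2
  med <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(med) || med <= 0) med <- 1
  exp(-d2 / med)
}

#' HSIC fitness of a gene subset
#'
#' The dependence between the masked submatrix's sample kernel and the label
#' kernel: the fitness the bat optimizer maximizes. With the default linear
#' gene kernel the value is additive over selected genes.
#'
#' @param X genes x samples matrix or `expr_matrix`.
#' @param mask logical vector (one entry per gene) selecting at least one gene.
#' @param y binary labels.
#' @param label_kernel `"delta"` or `"linear"`.
#' @param gene_kernel `"linear"` or `"rbf_median"`.
#' @return scalar HSIC value.
#' @export
subset_hsic <- function(X, mask, y, label_kernel = "delta",
                        gene_kernel = "linear") {
  X <- as_values(X)
  mask <- as.logical(mask)
  if (length(mask) != nrow(X))
    stop_ibosvm("mask must have one entry per gene", class = "ibosvm_shape_error")
  if (!any(mask))
    stop_ibosvm("mask selects no genes", class = "ibosvm_value_error")
  kind <- match.arg(label_kernel, c("delta", "linear"))
  y <- as.numeric(y)
  B <- if (kind == "delta") 1 * outer(y, y, `==`) else tcrossprod(y)
  K <- gene_kernel_matrix(X[mask, , drop = FALSE], gene_kernel)
  empirical_hsic(K, B)
}
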
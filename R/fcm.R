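# Fuzzy C-means partitioning of gene expression profiles.
#
# Genes are the items being clustered (rows of the expression matrix);
# prototypes live in sample space. The norm-inducing matrix A defaults to the
# identity, i.e. the standard Euclidean norm.

fcm_distances <- function(X, P, A = NULL) {
  # squared A-norm distances, genes x clusters
  if (is.null(A)) {
    d2 <- outer(rowSums(X^2), rep(1, nrow(P))) -
      2 * X %*% t(P) + outer(rep(1, nrow(X)), rowSums(P^2))
  } else {
    XA <- X %*% A
    PA <- P %*% A
    d2 <- outer(rowSums(XA * X), rep(1, nrow(P))) -
      2 * XA %*% t(P) + outer(rep(1, nrow(X)), rowSums(PA * P))
  }
  pmax(d2, 0)
}

#' Fuzzy C-means membership update
#'
#' Standard FCM membership update: for gene i and cluster j,
#' \eqn{\mu_{ij} = 1 / \sum_k (\|g_i - p_j\|_A / \|g_i - p_k\|_A)^{2/(m-1)}}.
#' A gene coinciding with one or more prototypes gets its full membership
#' split equally among the coincident prototypes (the standard zero-distance
#' singularity handling).
#'
#' @param X genes x samples numeric matrix (or an `expr_matrix`).
#' @param P clusters x samples prototype matrix.
#' @param m fuzzifier, must exceed 1.
#' @param A optional norm-inducing matrix (default identity).
#' @return clusters x genes membership matrix with columns summing to 1.
#' @export
membership_update <- function(X, P, m = 2, A = NULL) {
  X <- as_values(X)
  if (m <= 1)
    stop_ibosvm("fuzzifier m must be > 1 (got %g)", m, class = "ibosvm_param_error")
  d2 <- fcm_distances(X, P, A)              # genes x clusters
  U <- matrix(0, nrow(X), nrow(P))
  zero <- d2 <= .Machine$double.eps^0.9
  has_zero <- rowSums(zero) > 0
  if (any(has_zero))
    U[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  if (any(!has_zero)) {
    w <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
    U[!has_zero, ] <- w / rowSums(w)
  }
  t(U)                                      # clusters x genes
}

#' Fuzzy C-means prototype update
#'
#' Each prototype is the membership-weighted mean of the gene profiles:
#' \eqn{p_j = \sum_i \mu_{ij}^m g_i / \sum_i \mu_{ij}^m}.
#'
#' @param X genes x samples numeric matrix (or an `expr_matrix`).
#' @param U clusters x genes membership matrix.
#' @param m fuzzifier.
#' @return clusters x samples prototype matrix.
#' @export
prototype_update <- function(X, U, m = 2) {
  X <- as_values(X)
  W <- U^m
  totals <- rowSums(W)
  if (any(totals <= 0))
    stop_ibosvm("cluster %d has zero total membership", which(totals <= 0)[1],
                class = "ibosvm_degenerate_cluster")
  (W %*% X) / totals
}

#' Fuzzy C-means objective
#'
#' The weighted within-cluster sum of squared errors
#' \eqn{J_m = \sum_j \sum_i \mu_{ij}^m \|g_i - p_j\|_A^2}.
#'
#' @inheritParams prototype_update
#' @param P clusters x samples prototype matrix.
#' @param A optional norm-inducing matrix.
#' @return non-negative scalar.
#' @export
fcm_objective <- function(X, U, P, m = 2, A = NULL) {
  X <- as_values(X)
  d2 <- fcm_distances(X, P, A)      # genes x clusters
  sum(t(U^m) * d2)
}

#' Fit fuzzy C-means by alternating optimization
#'
#' Starts from a seeded uniform-random membership matrix (columns normalized
#' to sum to 1) and alternates [prototype_update()] / [membership_update()]
#' until the objective changes by less than `tol` or `max_iter` is reached.
#' The objective trace is non-increasing, a property asserted by the test
#' suite on every fit.
#'
#' @param X genes x samples matrix or `expr_matrix`; rows are clustered.
#' @param c number of clusters, `2 <= c <` number of genes.
#' @param m fuzzifier (> 1); larger values give softer partitions.
#' @param tol convergence threshold on the change in the objective.
#' @param max_iter iteration cap.
#' @param seed integer seed for the random initialization.
#' @param A optional norm-inducing matrix.
#' @return an object of class `fuzzy_partition`: membership matrix `U`
#'   (clusters x genes), prototypes `P`, `J_trace`, hard assignment
#'   `hard` (argmax membership, named by gene), and the call parameters.
#' @export
fcm_fit <- function(X, c, m = 2, tol = 1e-5, max_iter = 300, seed = 1, A = NULL) {
  Xv <- as_values(X)
  N <- nrow(Xv)
  if (c < 2 || c >= N)
    stop_ibosvm("need 2 <= c < number of genes (c=%d, N=%d)", c, N,
                class = "ibosvm_param_error")
  if (m <= 1) stop_ibosvm("fuzzifier m must be > 1", class = "ibosvm_param_error")
  if (tol <= 0) stop_ibosvm("tol must be positive", class = "ibosvm_param_error")

  if (!is.null(seed)) set.seed(seed)
  U <- matrix(stats::runif(c * N), c, N)
  U <- sweep(U, 2, colSums(U), "/")

  J_trace <- numeric(0)
  J_prev <- Inf
  for (iter in seq_len(max_iter)) {
    P <- prototype_update(Xv, U, m)
    U <- membership_update(Xv, P, m, A)
    J <- fcm_objective(Xv, U, P, m, A)
    J_trace <- c(J_trace, J)
    if (is.finite(J_prev) && abs(J_prev - J) < tol) break
    J_prev <- J
  }

  hard <- apply(U, 2, which.max)
  names(hard) <- rownames(Xv)
  structure(
    list(U = U, P = P, J_trace = J_trace, hard = hard,
         c = c, m = m, tol = tol, iterations = length(J_trace), seed = seed),
    class = "fuzzy_partition"
  )
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("fuzzy_partition: c=%d clusters, %d genes, m=%g, %d iterations, J=%.6g\n",
              x$c, ncol(x$U), x$m, x$iterations, utils::tail(x$J_trace, 1)))
  invisible(x)
}

#' Export a fuzzy partition as a table
#'
#' @param partition a `fuzzy_partition`.
#' @param path optional path; when given, written as TSV.
#' @return data.frame with gene_id, one membership column per cluster, and the
#'   hard (argmax) cluster label.
#' @export
export_partition <- function(partition, path = NULL) {
  U <- t(partition$U)
  df <- data.frame(gene_id = names(partition$hard), U,
                   hard_cluster = partition$hard, row.names = NULL,
                   check.names = FALSE)
  names(df)[2:(1 + partition$c)] <- paste0("mu_", seq_len(partition$c))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

as_values <- function(X) {
  if (inherits(X, "expr_matrix")) {
    if (any(X$missing_mask))
      stop_ibosvm("expression matrix contains missing values; run impute_missing first",
                  class = "ibosvm_value_error")
    X$values
  } else as.matrix(X)
}
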
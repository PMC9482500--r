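# Small in-code fixtures shared across tests.

# tiny labeled expression matrix with known values
tiny_expr <- function() {
  values <- matrix(c(1, 2, 3, 4,
                     4, 3, 2, 1,
                     0, 1, 0, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"),
                                   c("s1", "s2", "s3", "s4")))
  expression_matrix(values, labels = c(0, 0, 1, 1))
}

# two well-separated 1-D gene blobs (profiles along samples)
blob_matrix <- function(n_per = 10, centers = c(0, 10), sd = 0.2, seed = 1) {
  set.seed(seed)
  values <- rbind(
    matrix(rnorm(n_per * 3, centers[1], sd), n_per, 3),
    matrix(rnorm(n_per * 3, centers[2], sd), n_per, 3)
  )
  rownames(values) <- sprintf("g%02d", seq_len(2 * n_per))
  colnames(values) <- c("s1", "s2", "s3")
  values
}

# naive double-loop HSIC oracle: literally tr(HKHB) / (n-1)^2
hsic_oracle <- function(K, B) {
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  M <- H %*% K %*% H %*% B
  sum(diag(M)) / (n - 1)^2
}

# exhaustive PAM oracle: best medoid set over all size-k subsets
pam_oracle <- function(D, k) {
  n <- nrow(D)
  combs <- utils::combn(n, k)
  costs <- apply(combs, 2, function(med)
    sum(apply(D[, med, drop = FALSE], 1, min)))
  list(cost = min(costs), medoids = sort(combs[, which.min(costs)]))
}

expect_column_stochastic <- function(U, tol = 1e-9) {
  expect_true(all(U >= -tol & U <= 1 + tol))
  expect_equal(unname(colSums(U)), rep(1, ncol(U)), tolerance = tol)
}
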
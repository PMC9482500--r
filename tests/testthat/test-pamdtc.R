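test_that("dissimilarity transforms correlations entrywise", {
  R <- diag(2); R[1, 2] <- R[2, 1] <- 0
  expect_equal(dissimilarity(R)[1, 2], 1)
  R[1, 2] <- R[2, 1] <- 1
  expect_equal(dissimilarity(R)[1, 2], 0)

  set.seed(1)
  M <- matrix(rnorm(30), 10, 3)
  rownames(M) <- paste0("g", 1:10)
  R <- pearson_matrix(M)
  D_abs <- dissimilarity(R, "absolute")
  D_sgn <- dissimilarity(R, "signed")
  for (i in 1:10) for (j in 1:10) {
    if (i == j) next
    expect_equal(D_abs[i, j], 1 - abs(R[i, j]))
    expect_equal(D_sgn[i, j], 1 - R[i, j])
  }
  R[1, 2] <- R[2, 1] <- NA
  expect_error(dissimilarity(R), "g1")
})

test_that("dendrogram merges follow hand agglomeration", {
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- hierarchical_dendrogram(D2)
  expect_equal(h2$height, 3)

  # collinear points {0, 1, 10}, single linkage: merges at 1 then 9
  pts <- c(0, 1, 10)
  D3 <- as.matrix(dist(pts))
  rownames(D3) <- colnames(D3) <- c("p1", "p2", "p3")
  h3 <- hierarchical_dendrogram(D3, "single")
  expect_equal(h3$height, c(1, 9))
})

test_that("dendrogram is invariant to input gene order", {
  sim <- generate_dataset(n_genes = 12, n_samples = 15, n_informative = 0,
                          blocks = c(2, 5), missing_rate = 0, seed = 9)
  D <- dissimilarity(pearson_matrix(sim$expr))
  perm <- sample(nrow(D))
  h1 <- hierarchical_dendrogram(D)
  h2 <- hierarchical_dendrogram(D[perm, perm])
  expect_identical(h1$labels, h2$labels)
  expect_equal(h1$height, h2$height)
  expect_identical(h1$merge, h2$merge)
})

test_that("fixed-height cut brackets give one cluster or all singletons", {
  D <- as.matrix(dist(c(0, 0.2, 1, 1.3)))
  rownames(D) <- colnames(D) <- paste0("g", 1:4)
  dend <- hierarchical_dendrogram(D)
  expect_equal(length(unique(fixed_height_cut(dend, max(dend$height) + 1))), 1)
  expect_equal(length(unique(fixed_height_cut(dend, 0))), 4)

  # toy tree with merges at {0.2, 0.5, 0.9}: cut at 0.6 -> two clusters
  Dm <- matrix(0.9, 4, 4)
  Dm[1, 2] <- Dm[2, 1] <- 0.2
  Dm[3, 4] <- Dm[4, 3] <- 0.5
  diag(Dm) <- 0
  rownames(Dm) <- colnames(Dm) <- paste0("g", 1:4)
  cut <- fixed_height_cut(hierarchical_dendrogram(Dm), 0.6)
  expect_equal(length(unique(cut)), 2)
  expect_equal(cut[["g1"]], cut[["g2"]])
  expect_equal(cut[["g3"]], cut[["g4"]])
  expect_false(cut[["g1"]] == cut[["g3"]])
})

test_that("pam matches the exhaustive medoid oracle on 1-D points", {
  pts <- c(0, 1, 2, 10)
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("g", 1:4)
  fit <- pam(D, 2, seed = 1)
  oracle <- pam_oracle(D, 2)
  expect_equal(fit$cost, 2)
  expect_equal(oracle$cost, 2)
  expect_setequal(fit$medoids, rownames(D)[oracle$medoids])

  # k = n: every gene its own medoid at zero cost
  fit_n <- pam(D, 4, seed = 1)
  expect_equal(fit_n$cost, 0)
  expect_setequal(fit_n$medoids, rownames(D))
  expect_error(pam(D, 5), "k")
})

test_that("pam output is always a swap-local optimum (brute-force scan)", {
  for (s in 1:4) {
    sim <- generate_dataset(n_genes = 15, n_samples = 12, n_informative = 0,
                            blocks = c(3, 5), missing_rate = 0, seed = s)
    D <- dissimilarity(pearson_matrix(sim$expr))
    fit <- pam(D, 3, seed = s)
    med_idx <- match(fit$medoids, rownames(D))
    cost <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
    expect_equal(fit$cost, cost(med_idx))
    for (mi in seq_along(med_idx)) {
      for (x in setdiff(seq_len(nrow(D)), med_idx)) {
        cand <- med_idx; cand[mi] <- x
        expect_gte(cost(cand) - fit$cost, -1e-12)
      }
    }
    # nearest-medoid invariant
    for (g in seq_len(nrow(D))) {
      own <- fit$medoids[fit$modules[g]]
      expect_lte(D[g, own], min(D[g, fit$medoids]) + 1e-12)
    }
  }
})

test_that("pam agrees with the reference k-medoids solver on cost", {
  skip_if_not_installed("cluster")
  for (s in 1:3) {
    sim <- generate_dataset(n_genes = 18, n_samples = 14, n_informative = 0,
                            blocks = c(3, 6), rho = 0.8, missing_rate = 0,
                            seed = s)
    D <- dissimilarity(pearson_matrix(sim$expr))
    ours <- pam(D, 3, seed = s)
    ref <- cluster::pam(as.dist(D), 3)
    # both are local optima; ours must not be worse than the reference build
    expect_lte(ours$cost, ref$objective[["swap"]] * nrow(D) + 1e-8)
  }
})

test_that("pam_dtc recovers well-separated planted blocks", {
  sim <- generate_dataset(n_genes = 30, n_samples = 60, n_informative = 0,
                          blocks = list(1:10, 11:20, 21:30), rho = 0.95,
                          missing_rate = 0, seed = 10)
  D <- dissimilarity(pearson_matrix(sim$expr))
  ma <- pam_dtc(D, min_module_size = 5, seed = 1)
  expect_equal(length(ma$medoids), 3)
  for (b in sim$truth$blocks) {
    mods <- unique(ma$modules[b])
    expect_length(mods, 1)
  }
  # medoids belong to their own module; nearest-medoid invariant holds
  for (m in ma$medoids)
    expect_true(ma$modules[m] %in% ma$modules[names(ma$modules) == m])
  for (g in names(ma$modules)) {
    own <- ma$medoids[ma$modules[g]]
    expect_lte(D[g, own], min(D[g, ma$medoids]) + 1e-12)
  }
})

test_that("pam_dtc is seed-reproducible and handles a single tight cluster", {
  sim <- generate_dataset(n_genes = 8, n_samples = 40, n_informative = 0,
                          blocks = list(1:8), rho = 0.9, missing_rate = 0,
                          seed = 11)
  D <- dissimilarity(pearson_matrix(sim$expr))
  ma <- pam_dtc(D, min_module_size = 5, seed = 3)
  expect_equal(length(ma$medoids), 1)
  expect_equal(ma$outer_iterations, 1)

  ma2 <- pam_dtc(D, min_module_size = 5, seed = 3)
  expect_identical(ma$modules, ma2$modules)
  expect_identical(ma$medoids, ma2$medoids)
})

test_that("min_module_size = 1 disables merging", {
  D <- as.matrix(dist(c(0, 0.1, 5, 5.1, 10)))
  rownames(D) <- colnames(D) <- paste0("g", 1:5)
  ma <- pam_dtc(D, cut_height = 1, min_module_size = 1, seed = 1)
  expect_equal(length(ma$medoids), 3)  # {g1,g2}, {g3,g4}, {g5} survive
})

test_that("newick export preserves leaf depths", {
  D <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  nwk <- dendrogram_newick(hierarchical_dendrogram(D))
  expect_match(nwk, "^\\(a:3,b:3\\);$|^\\(b:3,a:3\\);$")
})
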
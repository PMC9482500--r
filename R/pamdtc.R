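# Module detection: correlation dissimilarity, hierarchical dendrogram,
# fixed-height cut, and partitioning around medoids (PAM) with the classical
# swap phase, iterated until the module set stabilizes.

#' Correlation-based dissimilarity
#'
#' Converts a gene correlation matrix to a dissimilarity: `1 - |r|`
#' (absolute mode, values in \[0, 1\]) or `1 - r` (signed, \[0, 2\]).
#' Undefined correlations (constant genes) are an error here — they cannot be
#' clustered meaningfully.
#'
#' @param R symmetric correlation matrix.
#' @param mode `"absolute"` or `"signed"`.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
dissimilarity <- function(R, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (anyNA(R)) {
    bad <- unique(rownames(R)[which(is.na(R), arr.ind = TRUE)[, 1]])
    stop_ibosvm("undefined correlations involving gene(s): %s",
                paste(bad, collapse = ", "), class = "ibosvm_value_error")
  }
  D <- if (mode == "absolute") 1 - abs(R) else 1 - R
  diag(D) <- 0
  D
}

#' Agglomerative dendrogram over genes
#'
#' Standard agglomerative clustering (stats::hclust) on a dissimilarity
#' matrix. Rows are reordered lexicographically by identifier before
#' agglomeration so the tree is invariant to the input gene order.
#'
#' @param D symmetric dissimilarity matrix with identifier dimnames.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return an `hclust` object.
#' @export
hierarchical_dendrogram <- function(D, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8))
    stop_ibosvm("dissimilarity matrix must be symmetric", class = "ibosvm_shape_error")
  D <- as.matrix(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("g", seq_len(nrow(D)))
  ord <- order(rownames(D))
  D <- D[ord, ord]
  stats::hclust(stats::as.dist(D), method = linkage)
}

#' Cut a dendrogram at a fixed height
#'
#' Removes all merges strictly above height `h`; the connected leaf groups
#' that remain are the initial clusters.
#'
#' @param dend an `hclust` object.
#' @param h cut height, `>= 0`.
#' @return named integer vector: cluster id per gene.
#' @export
fixed_height_cut <- function(dend, h) {
  if (h < 0) stop_ibosvm("cut height must be >= 0", class = "ibosvm_param_error")
  stats::cutree(dend, h = h)
}

#' Partitioning around medoids with random build phase
#'
#' k-medoids clustering as iterated medoid/non-medoid swapping: the build
#' phase draws k medoids at random (seeded); the swap phase computes, for
#' every (medoid m, non-medoid x) pair, the switching cost
#' `S = cost(after swapping m and x) - cost(current)` where cost is the total
#' dissimilarity of every item to its nearest medoid, performs the swap with
#' the most negative S (ties broken by lexicographic identifier pair), and
#' repeats while any `S < 0`. The total cost strictly decreases at every
#' executed swap, so termination is guaranteed.
#'
#' @param D symmetric dissimilarity matrix with identifier dimnames.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer seed for the random medoid draw.
#' @return a `module_assignment`: `modules` (named integer vector, gene ->
#'   module id), `medoids` (character, one per module), `cost`,
#'   `iterations` (number of executed swaps).
#' @export
pam <- function(D, k, seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("g", seq_len(n))
  if (k < 1 || k > n)
    stop_ibosvm("k must satisfy 1 <= k <= n (k=%d, n=%d)", k, n,
                class = "ibosvm_param_error")
  ids <- rownames(D)
  if (!is.null(seed)) set.seed(seed)
  medoids <- sort(sample.int(n, k))

  total_cost <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))

  cost <- total_cost(medoids)
  iterations <- 0L
  repeat {
    best_S <- 0
    best_swap <- NULL
    non_medoids <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      for (x in non_medoids) {
        cand <- medoids
        cand[mi] <- x
        S <- total_cost(cand) - cost
        if (S < best_S - 1e-12 ||
            (best_S < 0 && abs(S - best_S) <= 1e-12 && !is.null(best_swap) &&
             is_lex_smaller(ids[medoids[mi]], ids[x],
                            ids[best_swap[1]], ids[best_swap[2]]))) {
          best_S <- S
          best_swap <- c(medoids[mi], x)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[medoids == best_swap[1]] <- best_swap[2]
    cost <- cost + best_S
    iterations <- iterations + 1L
  }

  medoids <- sort(medoids)
  assign_idx <- apply(D[, medoids, drop = FALSE], 1, which.min)
  modules <- as.integer(assign_idx)
  names(modules) <- ids
  structure(
    list(modules = modules, medoids = ids[medoids], cost = cost,
         iterations = iterations, k = k, seed = seed),
    class = "module_assignment"
  )
}

is_lex_smaller <- function(a1, a2, b1, b2) {
  (a1 < b1) || (a1 == b1 && a2 < b2)
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module_assignment: %d genes in %d modules (cost %.4g)\n",
              length(x$modules), length(x$medoids), x$cost))
  invisible(x)
}

#' Module detection by fixed-height cut and iterated PAM
#'
#' The dendrogram over all genes is cut at a fixed height, producing an
#' initial set of large clusters. Each sufficiently large cluster is then
#' re-examined: its sub-dendrogram is rebuilt and cut at the same height,
#' and if that leaves it whole it is offered to [pam()] (k = `k_split`),
#' whose split is accepted only when the parts are genuinely separated —
#' mean between-part dissimilarity exceeding `split_ratio` times the mean
#' within-part dissimilarity. The procedure repeats until an iteration
#' creates no new cluster. Clusters smaller than `min_module_size` are
#' merged into the nearest module by medoid-to-medoid dissimilarity. The
#' result is finalized with nearest-medoid reassignment sweeps so that every
#' gene is at least as close to its own medoid as to any other.
#'
#' @param D symmetric dissimilarity matrix with identifier dimnames.
#' @param cut_height fixed cut height; default 0.99 x the root merge height.
#' @param min_module_size modules smaller than this are merged away
#'   (default 5); set to 1 to disable merging.
#' @param k_split PAM cluster count used when splitting a loose cluster
#'   (default 2, binary splitting with recursion via the outer loop).
#' @param split_ratio a PAM split is kept only when mean between-part
#'   dissimilarity > `split_ratio` x mean within-part dissimilarity
#'   (default 2); guards tight clusters against being broken up.
#' @param linkage linkage passed to [hierarchical_dendrogram()].
#' @param seed integer seed (PAM build phases).
#' @param max_outer safety cap on outer iterations.
#' @return a `module_assignment` with an extra `outer_iterations` field.
#' @export
pam_dtc <- function(D, cut_height = NULL, min_module_size = 5, k_split = 2,
                    split_ratio = 2, linkage = "average", seed = 1,
                    max_outer = 50) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("g", seq_len(nrow(D)))
  ids <- rownames(D)
  dend <- hierarchical_dendrogram(D, linkage)
  root_h <- max(dend$height)
  h <- cut_height %||% (0.99 * root_h)

  cut <- fixed_height_cut(dend, h)
  clusters <- split(names(cut), cut)
  if (!is.null(seed)) set.seed(seed)

  outer <- 0L
  repeat {
    outer <- outer + 1L
    changed <- FALSE
    next_clusters <- list()
    for (cl in clusters) {
      splittable <- length(cl) >= max(2, 2 * min_module_size)
      if (splittable) {
        sub_D <- D[cl, cl, drop = FALSE]
        sub_dend <- hierarchical_dendrogram(sub_D, linkage)
        sub_cut <- fixed_height_cut(sub_dend, min(h, max(sub_dend$height)))
        parts <- NULL
        if (length(unique(sub_cut)) > 1) {
          # the fixed-height cut itself separates the recomputed sub-tree
          parts <- split(names(sub_cut), sub_cut)
        } else {
          fit <- pam(sub_D, min(k_split, length(cl)), seed = NULL)
          cand <- Filter(length, split(names(fit$modules), fit$modules))
          if (length(cand) > 1 && split_separation(cand, D) > split_ratio)
            parts <- cand
        }
        if (!is.null(parts)) {
          next_clusters <- c(next_clusters, parts)
          changed <- TRUE
          next
        }
      }
      next_clusters <- c(next_clusters, list(cl))
    }
    clusters <- next_clusters

    # merging away undersized modules does not count as generating new
    # clusters, so it does not by itself keep the outer loop alive
    merged <- merge_small_modules(clusters, D, min_module_size)
    clusters <- merged$clusters

    if (!changed || outer >= max_outer) break
  }

  # finalize: medoids + nearest-medoid reassignment until stable
  for (sweep in 1:25) {
    medoids <- vapply(clusters, function(cl) cluster_medoid(cl, D), character(1))
    assign_idx <- apply(D[, medoids, drop = FALSE], 1, which.min)
    new_clusters <- split(ids, assign_idx)
    new_clusters <- Filter(length, new_clusters)
    sig <- function(cls) sort(vapply(cls, function(cl) paste(sort(cl), collapse = ","),
                                     character(1)))
    if (identical(sig(clusters), sig(new_clusters))) break
    clusters <- unname(new_clusters)
  }
  medoids <- sort(vapply(clusters, function(cl) cluster_medoid(cl, D), character(1)))
  assign_idx <- apply(D[, medoids, drop = FALSE], 1, which.min)
  modules <- as.integer(assign_idx)
  names(modules) <- ids
  cost <- sum(D[cbind(seq_along(ids), match(medoids[assign_idx], ids))])
  structure(
    list(modules = modules, medoids = medoids, cost = cost,
         iterations = NA_integer_, outer_iterations = outer,
         cut_height = h, min_module_size = min_module_size, seed = seed),
    class = "module_assignment"
  )
}

# ratio of mean between-part to mean within-part dissimilarity for a
# candidate split; 0 (refuse) when the parts carry no within-spread evidence
split_separation <- function(parts, D) {
  within <- unlist(lapply(parts, function(p) {
    if (length(p) < 2) return(NULL)
    sub <- D[p, p]
    sub[upper.tri(sub)]
  }))
  between <- unlist(lapply(seq_along(parts), function(i) {
    other <- unlist(parts[-i])
    as.vector(D[parts[[i]], other])
  }))
  if (is.null(within) || mean(within) == 0) return(0)
  mean(between) / mean(within)
}

cluster_medoid <- function(members, D) {
  members <- sort(members)
  totals <- colSums(D[members, members, drop = FALSE])
  members[which.min(totals)]
}

merge_small_modules <- function(clusters, D, min_module_size) {
  changed <- FALSE
  repeat {
    sizes <- lengths(clusters)
    if (length(clusters) <= 1 || all(sizes >= min_module_size)) break
    i <- which.min(sizes)
    medoids <- vapply(clusters, function(cl) cluster_medoid(cl, D), character(1))
    d_to_others <- D[medoids[i], medoids]
    d_to_others[i] <- Inf
    j <- which.min(d_to_others)
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    clusters[[i]] <- NULL
    changed <- TRUE
  }
  list(clusters = clusters, changed = changed)
}

#' Export a module assignment as a table
#'
#' @param ma a `module_assignment`.
#' @param path optional TSV output path.
#' @return data.frame with gene_id, module_id and a medoid flag.
#' @export
export_modules <- function(ma, path = NULL) {
  df <- data.frame(
    gene_id = names(ma$modules),
    module_id = unname(ma$modules),
    is_medoid = names(ma$modules) %in% ma$medoids,
    stringsAsFactors = FALSE
  )
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

#' Export an hclust dendrogram as Newick text
#'
#' Branch lengths are differences between successive merge heights, so leaf
#' depths equal the merge heights of the original tree.
#'
#' @param dend an `hclust` object.
#' @param path optional output path.
#' @return the Newick string, invisibly when writing to a file.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  build <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%.10g", dend$labels[-node], parent_h)
    } else {
      h <- dend$height[node]
      left <- build(dend$merge[node, 1], h)
      right <- build(dend$merge[node, 2], h)
      sprintf("(%s,%s):%.10g", left, right, parent_h - h)
    }
  }
  root <- nrow(dend$merge)
  nwk <- paste0(sub(":[^:]*$", "", build(root, dend$height[root])), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
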
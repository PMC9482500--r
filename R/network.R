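# Coexpression networks: Pearson correlation, hard thresholding, and the
# differential network between two biological states.

#' Pearson correlation matrix over genes
#'
#' Correlates gene profiles across samples, optionally restricted to the
#' samples of one class label. Genes with zero variance in the subset yield
#' undefined correlations; these are returned as `NA` and flagged in the
#' `"constant_genes"` attribute rather than silently zeroed.
#'
#' @param x an `expr_matrix` (no missing values) or genes x samples matrix.
#' @param sample_subset optional label (0 or 1) restricting the samples used.
#' @return symmetric genes x genes correlation matrix, diagonal 1, with a
#'   `constant_genes` attribute naming zero-variance genes (if any).
#' @export
pearson_matrix <- function(x, sample_subset = NULL) {
  values <- as_values(x)
  if (!is.null(sample_subset)) {
    if (!inherits(x, "expr_matrix") || is.null(x$labels))
      stop_ibosvm("sample_subset requires a labeled expr_matrix",
                  class = "ibosvm_param_error")
    values <- values[, x$labels == sample_subset, drop = FALSE]
  }
  if (ncol(values) < 3)
    stop_ibosvm("need at least 3 samples to correlate (got %d)", ncol(values),
                class = "ibosvm_param_error")
  constant <- apply(values, 1, stats::sd) == 0
  R <- suppressWarnings(stats::cor(t(values), method = "pearson"))
  diag(R) <- 1
  attr(R, "constant_genes") <- rownames(values)[constant]
  R
}

#' Build a coexpression network by hard thresholding
#'
#' Links gene pairs whose correlation strictly exceeds the threshold `tau`
#' (default 0.8): `r > tau` in signed mode, `|r| > tau` in absolute mode.
#' The boundary is exclusive — a pair at exactly `tau` is not linked.
#'
#' @param R symmetric correlation matrix with gene identifiers as dimnames.
#' @param tau correlation threshold in \[0, 1\].
#' @param mode `"absolute"` (default, sign-agnostic as in coexpression-module
#'   practice) or `"signed"`.
#' @return a `gene_network`: list with `nodes`, an `edges` data.frame
#'   (`gene_a < gene_b` by identifier, columns gene_a, gene_b, r), `tau`,
#'   `mode`.
#' @export
threshold_network <- function(R, tau = 0.8, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (tau < 0 || tau > 1)
    stop_ibosvm("tau must lie in [0, 1] (got %g)", tau, class = "ibosvm_param_error")
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop_ibosvm("correlation matrix must be symmetric", class = "ibosvm_shape_error")
  nodes <- rownames(R) %||% paste0("g", seq_len(nrow(R)))
  crit <- if (mode == "absolute") abs(R) else R
  crit[is.na(crit)] <- -Inf
  idx <- which(upper.tri(crit) & crit > tau, arr.ind = TRUE)
  edges <- data.frame(
    gene_a = nodes[idx[, 1]], gene_b = nodes[idx[, 2]],
    r = R[idx], stringsAsFactors = FALSE
  )
  # canonical order: a < b lexicographically, rows sorted
  flip <- edges$gene_a > edges$gene_b
  if (any(flip)) {
    tmp <- edges$gene_a[flip]
    edges$gene_a[flip] <- edges$gene_b[flip]
    edges$gene_b[flip] <- tmp
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, tau = tau, mode = mode),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges (tau=%g, %s mode)\n",
              length(x$nodes), nrow(x$edges), x$tau, x$mode))
  invisible(x)
}

#' Differential coexpression network between two states
#'
#' Edges coexpressed in exactly one of the two state networks (the symmetric
#' difference of the edge sets), each annotated with the state it came from.
#'
#' @param net_a,net_b `gene_network` objects over the same node set, e.g. the
#'   normal-state and tumor-state networks.
#' @param states length-2 character vector naming the two states.
#' @return a `gene_network` whose `edges` carry an extra `state` column.
#' @export
differential_network <- function(net_a, net_b, states = c("a", "b")) {
  stopifnot(inherits(net_a, "gene_network"), inherits(net_b, "gene_network"))
  if (!setequal(net_a$nodes, net_b$nodes)) {
    only_a <- setdiff(net_a$nodes, net_b$nodes)
    only_b <- setdiff(net_b$nodes, net_a$nodes)
    stop_ibosvm("node sets differ (only in first: %s; only in second: %s)",
                paste(only_a, collapse = ","), paste(only_b, collapse = ","),
                class = "ibosvm_value_error")
  }
  key <- function(e) paste(e$gene_a, e$gene_b, sep = "\r")
  ka <- key(net_a$edges); kb <- key(net_b$edges)
  ea <- net_a$edges[!(ka %in% kb), , drop = FALSE]
  eb <- net_b$edges[!(kb %in% ka), , drop = FALSE]
  if (nrow(ea)) ea$state <- states[1]
  else ea$state <- character(0)
  if (nrow(eb)) eb$state <- states[2]
  else eb$state <- character(0)
  edges <- rbind(ea, eb)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(net_a$nodes), edges = edges,
                 tau = net_a$tau, mode = net_a$mode),
            class = "gene_network")
}

#' Export network edges as TSV
#'
#' @param net a `gene_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
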
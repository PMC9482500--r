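# Binary bat optimizer for HSIC-guided gene selection.
#
# Each bat carries a continuous position over candidate genes, a velocity, a
# frequency draw, a loudness and a pulse rate. Positions are binarized to a
# fixed-cardinality mask (top-k coordinates) before fitness evaluation; the
# global best (Gbest) is elitist over every mask ever evaluated.

#' Initialize a bat swarm
#'
#' @param n_genes number of candidate genes (position dimension).
#' @param n_bats swarm size.
#' @param k mask cardinality used at binarization.
#' @param fitness function(mask) -> scalar to maximize.
#' @param gene_ids identifiers used for deterministic tie-breaking.
#' @param fr_range frequency range `c(Fr_min, Fr_max)`.
#' @param loudness0 initial loudness A0.
#' @param pulse0 initial pulse rate r0.
#' @param alpha loudness decay factor.
#' @param gamma pulse-rate growth rate.
#' @param loudness_min floor on the loudness, which also scales the local
#'   walk: keeping it positive keeps late-stage walks able to swap single
#'   genes in and out of the mask.
#' @return a `bat_swarm` object (positions, velocities, per-bat state, Gbest).
#' @export
bat_swarm <- function(n_genes, n_bats, k, fitness, gene_ids = NULL,
                      fr_range = c(0, 2), loudness0 = 1, pulse0 = 0.5,
                      alpha = 0.9, gamma = 0.9, loudness_min = 0.05) {
  gene_ids <- gene_ids %||% sprintf("g%05d", seq_len(n_genes))
  positions <- matrix(stats::runif(n_bats * n_genes), n_bats, n_genes)
  velocities <- matrix(0, n_bats, n_genes)
  fit <- numeric(n_bats)
  best_fit <- -Inf
  best_pos <- NULL
  best_mask <- NULL
  for (i in seq_len(n_bats)) {
    mask <- binarize_topk(positions[i, ], k, gene_ids)
    fit[i] <- fitness(mask)
    if (fit[i] > best_fit) {
      best_fit <- fit[i]
      best_pos <- positions[i, ]
      best_mask <- mask
    }
  }
  structure(
    list(positions = positions, velocities = velocities, fitness = fit,
         loudness = rep(loudness0, n_bats), pulse = rep(pulse0, n_bats),
         gbest = list(position = best_pos, mask = best_mask, fitness = best_fit),
         k = k, gene_ids = gene_ids, fr_range = fr_range,
         loudness0 = loudness0, pulse0 = pulse0, alpha = alpha, gamma = gamma,
         loudness_min = loudness_min, t = 0L),
    class = "bat_swarm"
  )
}

#' Binarize a continuous position to a fixed-size mask
#'
#' Keeps the k largest coordinates; ties are broken by lexicographic gene
#' identifier so the mask is deterministic.
#'
#' @param position numeric vector.
#' @param k number of genes to keep.
#' @param gene_ids identifiers for tie-breaking.
#' @return logical mask with exactly k `TRUE` entries.
#' @export
binarize_topk <- function(position, k, gene_ids = NULL) {
  gene_ids <- gene_ids %||% sprintf("g%05d", seq_along(position))
  keep <- order(-position, gene_ids)[seq_len(k)]
  mask <- logical(length(position))
  mask[keep] <- TRUE
  mask
}

#' Advance a bat swarm by one iteration
#'
#' For each bat in fixed order: draw a frequency
#' `Fr = Fr_min + (Fr_max - Fr_min) * beta`, `beta ~ U(0,1)`; update the
#' velocity `Ve <- Ve + (gf - Gbest) * Fr` and the candidate position
#' `gf + Ve`, clamped to the unit box (velocity coordinates that hit a bound
#' are reset to zero, the usual bound handling that keeps the flight from
#' diverging); with probability `1 - r_i` replace the candidate by a local
#' walk around the global best, `Gbest + eps * mean(loudness)` with
#' `eps ~ U(-1, 1)` per coordinate; binarize and evaluate. The candidate is
#' accepted (position and fitness replaced, loudness decayed by `alpha` down
#' to `loudness_min`, pulse rate raised toward `r0`) only when it improves
#' the bat's fitness and `U(0,1) < A_i`. Gbest is updated from every
#' evaluation, so the best-ever fitness never decreases.
#'
#' @param swarm a `bat_swarm`.
#' @param fitness function(mask) -> scalar.
#' @return the advanced `bat_swarm`.
#' @export
bat_step <- function(swarm, fitness) {
  stopifnot(inherits(swarm, "bat_swarm"))
  n_bats <- nrow(swarm$positions)
  p <- ncol(swarm$positions)
  swarm$t <- swarm$t + 1L
  # deterministic cooling: loudness decays once per iteration for every bat
  # (floored), so the walk sparsifies from global exploration to single-gene
  # swaps on a fixed schedule instead of waiting on acceptances
  swarm$loudness <- pmax(swarm$alpha * swarm$loudness, swarm$loudness_min)
  for (i in seq_len(n_bats)) {
    fr <- swarm$fr_range[1] + diff(swarm$fr_range) * stats::runif(1)
    v <- swarm$velocities[i, ] +
      (swarm$positions[i, ] - swarm$gbest$position) * fr
    candidate <- swarm$positions[i, ] + v
    out_of_box <- candidate < 0 | candidate > 1
    v[out_of_box] <- 0
    candidate <- reflect_unit(candidate)
    swarm$velocities[i, ] <- v
    if (stats::runif(1) > swarm$pulse[i]) {
      # local walk around the global best: the mean loudness sets the
      # fraction of coordinates kicked (dense early = exploration, sparse
      # late = single-gene swaps in the binarized mask); kicks span the full
      # position range so any gene can enter or leave the mask
      kick <- stats::runif(p) < mean(swarm$loudness)
      candidate <- swarm$gbest$position
      candidate[kick] <- candidate[kick] +
        stats::runif(sum(kick), -1, 1) * swarm$loudness0
      candidate <- reflect_unit(candidate)
    }
    mask <- binarize_topk(candidate, swarm$k, swarm$gene_ids)
    f <- fitness(mask)
    if (f > swarm$fitness[i] && stats::runif(1) < swarm$loudness[i]) {
      swarm$positions[i, ] <- candidate
      swarm$fitness[i] <- f
      swarm$pulse[i] <- swarm$pulse0 * (1 - exp(-swarm$gamma * swarm$t))
    }
    if (f > swarm$gbest$fitness) {
      swarm$gbest <- list(position = candidate, mask = mask, fitness = f)
    }
  }
  swarm
}

#' Gene selection by HSIC maximization with the bat algorithm
#'
#' Runs the binary bat optimizer for `n_iter` iterations over the candidate
#' genes of `X`, maximizing [subset_hsic()] at fixed cardinality `k`. The
#' returned weight vector `u` is the best mask normalized to unit length
#' (`u = mask / sqrt(k)`), enforcing sparsity with a unit-norm constraint.
#' Fully reproducible from `seed`.
#'
#' @param X genes x samples matrix or `expr_matrix` of candidate genes.
#' @param y binary labels (0/1), one per sample.
#' @param k number of genes to select.
#' @param n_bats swarm size (default 30).
#' @param n_iter iterations (default 100).
#' @param seed integer seed.
#' @param label_kernel,gene_kernel kernels passed to [subset_hsic()].
#' @param fr_range,loudness0,pulse0,alpha,gamma bat schedule parameters.
#' @return a `selection_result`: logical `mask` named by gene, `u`,
#'   `hsic_score`, best-fitness `trajectory` (length `n_iter + 1`), `seed`,
#'   `iterations`, and the selected `gene_ids`.
#' @export
ibo_select <- function(X, y, k, n_bats = 30, n_iter = 100, seed = 1,
                       label_kernel = "delta", gene_kernel = "linear",
                       fr_range = c(0, 2), loudness0 = 1, pulse0 = 0.5,
                       alpha = 0.9, gamma = 0.9) {
  Xv <- as_values(X)
  p <- nrow(Xv)
  if (k < 1 || k > p)
    stop_ibosvm("k must satisfy 1 <= k <= %d (got %d)", p, k,
                class = "ibosvm_param_error")
  if (length(y) != ncol(Xv))
    stop_ibosvm("y must have one label per sample", class = "ibosvm_shape_error")
  gene_ids <- rownames(Xv) %||% sprintf("g%05d", seq_len(p))

  B <- label_kernel_matrix(y, label_kernel)
  fitness <- function(mask) {
    K <- gene_kernel_matrix(Xv[mask, , drop = FALSE], gene_kernel)
    empirical_hsic(K, B)
  }

  if (!is.null(seed)) set.seed(seed)
  swarm <- bat_swarm(p, n_bats, k, fitness, gene_ids,
                     fr_range = fr_range, loudness0 = loudness0,
                     pulse0 = pulse0, alpha = alpha, gamma = gamma)
  trajectory <- numeric(n_iter + 1)
  trajectory[1] <- swarm$gbest$fitness
  for (iter in seq_len(n_iter)) {
    swarm <- bat_step(swarm, fitness)
    trajectory[iter + 1] <- swarm$gbest$fitness
  }

  mask <- swarm$gbest$mask
  names(mask) <- gene_ids
  u <- mask / sqrt(k)
  structure(
    list(mask = mask, u = as.numeric(u), hsic_score = swarm$gbest$fitness,
         trajectory = trajectory, seed = seed, iterations = n_iter,
         gene_ids = gene_ids[mask], k = k,
         label_kernel = label_kernel, gene_kernel = gene_kernel),
    class = "selection_result"
  )
}

# reflect positions back into [0, 1]: avoids the saturation at the bounds
# that clamping would cause, which under rank-based binarization piles
# coordinates onto ties
reflect_unit <- function(x) {
  x <- abs(x)
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

label_kernel_matrix <- function(y, kind) {
  y <- as.numeric(y)
  kind <- match.arg(kind, c("delta", "linear"))
  if (kind == "delta") 1 * outer(y, y, `==`) else tcrossprod(y)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d/%d genes, HSIC score %.6g (seed %s)\n",
              x$k, length(x$mask), x$hsic_score, format(x$seed)))
  cat("  selected:", paste(utils::head(x$gene_ids, 10), collapse = ", "),
      if (length(x$gene_ids) > 10) "..." else "", "\n")
  invisible(x)
}

#' Export a selection result
#'
#' Writes a per-gene TSV (gene_id, selected flag, weight) and optionally a
#' JSON run-metadata file (seed, parameters, score trajectory).
#'
#' @param sel a `selection_result`.
#' @param path TSV output path (optional).
#' @param json_path JSON metadata path (optional).
#' @return the per-gene data.frame.
#' @export
export_selection <- function(sel, path = NULL, json_path = NULL) {
  df <- data.frame(gene_id = names(sel$mask), selected = unname(sel$mask),
                   weight = sel$u, stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    meta <- list(seed = sel$seed, k = sel$k, iterations = sel$iterations,
                 label_kernel = sel$label_kernel, gene_kernel = sel$gene_kernel,
                 hsic_score = sel$hsic_score, trajectory = sel$trajectory,
                 selected = sel$gene_ids)
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  df
}
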
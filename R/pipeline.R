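# End-to-end orchestration: normalize -> FCM -> state networks -> modules ->
# HSIC/bat gene selection -> nested-CV SVM -> reports, driven by a single
# declarative config with a mandatory seed. Every stage writes its artifact
# so stages can also be run standalone.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every default filled in. Any
#' subset of fields can be overridden via `...` (or by the YAML config a CLI
#' run supplies); the seed has no default and must be given.
#'
#' @param seed mandatory integer seed.
#' @param ... overrides for any configuration field.
#' @return a named list (`pipeline_config`).
#' @export
pipeline_config <- function(seed, ...) {
  if (missing(seed) || is.null(seed))
    stop_ibosvm("config field 'seed' is required", class = "ibosvm_config_error")
  cfg <- list(
    seed = as.integer(seed),
    input = NULL,                      # path; NULL = simulate
    format = "matrix_tsv",             # or two_channel_tsv
    normalization = list(summary = "median", background_subtract = FALSE),
    simulate = list(n_genes = 200, n_samples = 60, n_informative = 10,
                    blocks = c(4, 25), rho = 0.7, effect_size = 1.5,
                    noise_sd = 1, missing_rate = 0.01),
    fcm = list(c = 4, m = 2, tol = 1e-5, max_iter = 300),
    network = list(tau = 0.8, mode = "absolute"),
    pamdtc = list(cut_height = NULL, min_module_size = 5, k_split = 2,
                  linkage = "average"),
    selection = list(k = 10, n_bats = 30, n_iter = 100,
                     label_kernel = "delta", gene_kernel = "linear",
                     candidates = "all"),  # all | medoids | differential
    classifier = list(kernel = "rbf", C = 1),
    cv = list(folds = 5),
    out_dir = NULL
  )
  overrides <- list(...)
  modifyList(cfg, overrides)
}

validate_config <- function(cfg) {
  required <- c("seed", "fcm", "network", "pamdtc", "selection",
                "classifier", "cv")
  missing_f <- setdiff(required, names(cfg))
  if (length(missing_f))
    stop_ibosvm("config missing required field(s): %s",
                paste(missing_f, collapse = ", "),
                class = "ibosvm_config_error")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop_ibosvm("input file does not exist: %s", cfg$input,
                class = "ibosvm_config_error")
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes every stage in order — normalization/imputation, fuzzy C-means
#' partitioning, per-state coexpression networks and their differential
#' network, PAM-based module detection, HSIC/bat gene selection, and nested
#' cross-validated SVM evaluation — writing each intermediate artifact plus a
#' machine-readable run manifest. Identical config + seed gives identical
#' outputs (timings aside).
#'
#' @param config a list from [pipeline_config()] (fields may come from YAML).
#' @return invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_ibosvm("pipeline stage '%s' failed: %s", name, conditionMessage(e),
                  class = "ibosvm_stage_error")
    })
  }

  # -- input / normalization ------------------------------------------------
  input <- stage("input", {
    if (is.null(cfg$input)) {
      sim <- do.call(generate_dataset, c(cfg$simulate, list(seed = cfg$seed)))
      emit("ground_truth.json", function(p) write_ground_truth(sim$truth, p))
      list(expr = sim$expr, truth = sim$truth)
    } else if (cfg$format == "two_channel_tsv") {
      tab <- read_expression_table(cfg$input, "two_channel_tsv")
      list(expr = log_ratio_normalize(
        tab, summary = cfg$normalization$summary,
        background_subtract = cfg$normalization$background_subtract),
        truth = NULL)
    } else {
      list(expr = read_expression_table(cfg$input, "matrix_tsv"), truth = NULL)
    }
  })
  expr <- input$expr
  truth <- input$truth
  expr <- stage("impute", impute_missing(expr))
  emit("expression.tsv", function(p) write_expression_matrix(expr, p))
  if (is.null(expr$labels))
    stop_ibosvm("pipeline stage 'input' failed: sample labels are required",
                class = "ibosvm_stage_error")

  # -- fuzzy C-means partition ---------------------------------------------
  partition <- stage("fcm", fcm_fit(expr, c = cfg$fcm$c, m = cfg$fcm$m,
                                    tol = cfg$fcm$tol,
                                    max_iter = cfg$fcm$max_iter,
                                    seed = cfg$seed))
  emit("fcm_partition.tsv", function(p) { export_partition(partition, p); p })

  # -- per-state networks + differential network ----------------------------
  nets <- stage("network", {
    R_normal <- pearson_matrix(expr, sample_subset = 0)
    R_tumor <- pearson_matrix(expr, sample_subset = 1)
    net_normal <- threshold_network(R_normal, cfg$network$tau, cfg$network$mode)
    net_tumor <- threshold_network(R_tumor, cfg$network$tau, cfg$network$mode)
    diff_net <- differential_network(net_normal, net_tumor,
                                     states = c("normal", "tumor"))
    list(normal = net_normal, tumor = net_tumor, differential = diff_net)
  })
  emit("network_normal.tsv", function(p) write_network(nets$normal, p))
  emit("network_tumor.tsv", function(p) write_network(nets$tumor, p))
  emit("network_differential.tsv", function(p) write_network(nets$differential, p))

  # -- module detection -----------------------------------------------------
  modules <- stage("modules", {
    R_all <- pearson_matrix(expr)
    D <- dissimilarity(R_all, mode = cfg$network$mode)
    pam_dtc(D, cut_height = cfg$pamdtc$cut_height,
            min_module_size = cfg$pamdtc$min_module_size,
            k_split = cfg$pamdtc$k_split, linkage = cfg$pamdtc$linkage,
            seed = cfg$seed)
  })
  emit("modules.tsv", function(p) { export_modules(modules, p); p })

  # -- gene selection on the configured candidate set -----------------------
  candidates <- stage("candidates", switch(
    cfg$selection$candidates,
    all = expr$gene_ids,
    medoids = modules$medoids,
    differential = sort(unique(c(nets$differential$edges$gene_a,
                                 nets$differential$edges$gene_b))),
    stop_ibosvm("unknown candidate set '%s'", cfg$selection$candidates,
                class = "ibosvm_config_error")
  ))
  if (length(candidates) < cfg$selection$k)
    candidates <- expr$gene_ids  # candidate set smaller than k: fall back
  selection <- stage("select", {
    Xc <- expr$values[candidates, , drop = FALSE]
    ibo_select(Xc, expr$labels, k = cfg$selection$k,
               n_bats = cfg$selection$n_bats, n_iter = cfg$selection$n_iter,
               seed = cfg$seed,
               label_kernel = cfg$selection$label_kernel,
               gene_kernel = cfg$selection$gene_kernel)
  })
  emit("selection.tsv", function(p) { export_selection(selection, p); p })
  emit("selection_meta.json",
       function(p) { export_selection(selection, json_path = p); p })

  # -- nested cross-validated evaluation ------------------------------------
  report <- stage("classify", cross_validate(
    expr, expr$labels, folds = cfg$cv$folds, seed = cfg$seed,
    select_k = cfg$selection$k, n_bats = cfg$selection$n_bats,
    n_iter = cfg$selection$n_iter, kernel = cfg$classifier$kernel,
    C = cfg$classifier$C, label_kernel = cfg$selection$label_kernel,
    gene_kernel = cfg$selection$gene_kernel
  ))
  emit("report.json", function(p) {
    jsonlite::write_json(list(
      precision = report$precision, recall = report$recall,
      f_measure = report$f_measure, specificity = report$specificity,
      accuracy = report$accuracy, auc = report$auc,
      mean_tpr = report$mean_tpr,
      counts = unclass(report$counts)
    ), p, auto_unbox = TRUE, digits = NA)
    p
  })
  emit("roc.tsv", function(p) {
    utils::write.table(report$roc, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  })

  manifest <- list(
    package = "ibosvm",
    version = as.character(utils::packageVersion("ibosvm")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_genes = nrow(expr$values), n_samples = ncol(expr$values),
    n_modules = length(modules$medoids),
    n_differential_edges = nrow(nets$differential$edges),
    selected_genes = selection$gene_ids,
    hsic_score = selection$hsic_score,
    metrics = list(precision = report$precision, recall = report$recall,
                   f_measure = report$f_measure,
                   specificity = report$specificity,
                   accuracy = report$accuracy, auc = report$auc)
  )
  emit("manifest.json", function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
    p
  })

  invisible(list(expr = expr, truth = truth, partition = partition,
                 networks = nets, modules = modules, selection = selection,
                 report = report, manifest = manifest))
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file; must define `seed`.
#' @return a validated config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed))
    stop_ibosvm("config missing required field(s): seed",
                class = "ibosvm_config_error")
  cfg <- do.call(pipeline_config, raw)
  validate_config(cfg)
}
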
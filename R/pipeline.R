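# Orchestration: configuration, per-gene experiment runs, result tables and
# the run manifest. Each stage is an exported function so the stages are
# independently scriptable; run_experiment() ties them together.

#' Build and validate a run configuration
#'
#' @param mode Generalization design: `"cross_dataset"` or
#'   `"cancer_type_holdout"`.
#' @param model `"linear"` (L1-penalized logistic regression over the C
#'   grid) or `"mlp"` (3-layer network over a regularization axis).
#' @param train_context,test_context Dataset labels (cross_dataset) or the
#'   training dataset's label plus the held-out cancer type
#'   (cancer_type_holdout).
#' @param axis Regularization axis; defaults to `"C"` for linear and
#'   `"hidden_size"` for mlp.
#' @param grid Axis values; defaults to the axis's standard grid.
#' @param n_folds,n_seeds Cross-validation design (defaults 4 x 2 for
#'   linear, 4 x 1 for mlp).
#' @param genes Optional subset of target genes to analyse.
#' @param synthetic A [cohort_config()] (or its argument list) to generate
#'   inputs, or `NULL` when reading files.
#' @param paths Named list of input files for [read_cohort_inputs()] when
#'   `synthetic` is `NULL`.
#' @param gene_roles Data frame (gene, role) for file-based inputs;
#'   synthetic cohorts carry their own.
#' @param cnv_dialect,deep_only CNV handling for file-based inputs.
#' @param hyperparameters Fixed MLP hyperparameters (skips tuning).
#' @param output_dir Directory for result tables; `NULL` keeps results in
#'   memory only.
#' @param seed Base seed for model training.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = "cross_dataset", model = "linear",
                       train_context = "context_1", test_context = NULL,
                       axis = NULL, grid = NULL,
                       n_folds = 4L, n_seeds = if (model == "mlp") 1L else 2L,
                       genes = NULL, synthetic = NULL, paths = NULL,
                       gene_roles = NULL,
                       cnv_dialect = "continuous", deep_only = TRUE,
                       hyperparameters = NULL, output_dir = NULL, seed = 1L) {
  if (!mode %in% c("cross_dataset", "cancer_type_holdout")) {
    stop_config("unknown mode '%s'", mode)
  }
  if (!model %in% c("linear", "mlp")) stop_config("unknown model '%s'", model)
  axis <- axis %||% if (model == "linear") "C" else "hidden_size"
  if (model == "linear" && axis != "C") {
    stop_config("linear models sweep the C axis only")
  }
  axis_orientation(axis) # validates the axis name
  if (is.null(synthetic) && is.null(paths)) {
    stop_config("either 'synthetic' or 'paths' input must be given")
  }
  if (!is.null(paths)) {
    need <- c("expression", "mutations", "cnv", "annotations")
    missing <- setdiff(need, names(paths))
    if (length(missing) > 0) {
      stop_config("paths missing entries: %s", paste(missing, collapse = ", "))
    }
    absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(absent) > 0) {
      stop_config("input file(s) not found: %s", paste(absent, collapse = ", "))
    }
    if (is.null(gene_roles)) {
      stop_config("file-based inputs need 'gene_roles' (gene, role)")
    }
  }
  if (!is.null(synthetic) && !inherits(synthetic, "cohort_config")) {
    synthetic <- do.call(cohort_config, synthetic)
  }
  structure(list(mode = mode, model = model, axis = axis, grid = grid,
                 train_context = train_context, test_context = test_context,
                 n_folds = as.integer(n_folds), n_seeds = as.integer(n_seeds),
                 genes = genes, synthetic = synthetic, paths = paths,
                 gene_roles = gene_roles, cnv_dialect = cnv_dialect,
                 deep_only = deep_only, hyperparameters = hyperparameters,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Per-measurement generalization records at one parameter
#'
#' For the given axis value, pairs each (seed, fold) holdout measurement
#' with its test measurement and computes the baseline-corrected difference
#' corrected(holdout) - corrected(test); each term is corrected with its own
#' evaluation set's prevalence. Positive differences mean poor
#' generalization.
#'
#' @param sweep A `sweep_result` for one gene.
#' @param param The axis value to extract (typically the best-selected one).
#' @return A tibble: `gene`, `context`, `param`, `seed`, `fold`,
#'   `holdout_aupr`, `holdout_prevalence`, `test_aupr`, `test_prevalence`,
#'   `corrected_holdout`, `corrected_test`, `difference`.
#' @export
generalization_records <- function(sweep, param) {
  # the duplicated 1e3 grid entry yields two identical rows per measurement;
  # keep one so the holdout/test pairing stays one-to-one
  sweep <- dplyr::distinct(sweep, .data$gene, .data$context, .data$param,
                           .data$seed, .data$fold, .data$role,
                           .keep_all = TRUE)
  h <- sweep[sweep$role == "holdout" & sweep$param == param, , drop = FALSE]
  t_ <- sweep[sweep$role == "test" & sweep$param == param, , drop = FALSE]
  merged <- dplyr::inner_join(
    dplyr::select(h, "gene", "context", "param", "seed", "fold",
                  holdout_aupr = "aupr", holdout_prevalence = "prevalence"),
    dplyr::select(t_, "gene", "context", "param", "seed", "fold",
                  test_aupr = "aupr", test_prevalence = "prevalence"),
    by = c("gene", "context", "param", "seed", "fold"))
  merged <- merged[!is.na(merged$holdout_aupr) & !is.na(merged$test_aupr), ,
                   drop = FALSE]
  if (nrow(merged) == 0L) stop_data("no paired holdout/test measurements at param %s", param)
  merged$corrected_holdout <- corrected_aupr(merged$holdout_aupr,
                                             merged$holdout_prevalence)
  merged$corrected_test <- corrected_aupr(merged$test_aupr,
                                          merged$test_prevalence)
  merged$difference <- merged$corrected_holdout - merged$corrected_test
  merged
}

# Restrict a gene's cohort to its valid cancer types: training/holdout pool
# to the train context's valid types; the test side to the test context
# (valid types there in cross_dataset mode, the held-out type itself in
# cancer_type_holdout mode). Returns NULL (with a reason) when the gene
# fails the retention rule.
restrict_gene_cohort <- function(annotations, labels, config) {
  ann <- annotations
  if (config$mode == "cross_dataset") {
    tr <- ann[ann$context == config$train_context, , drop = FALSE]
    te <- ann[ann$context == config$test_context, , drop = FALSE]
    vt_train <- valid_cancer_types(labels[tr$sample_id], tr$cancer_type)
    vt_test <- valid_cancer_types(labels[te$sample_id], te$cancer_type)
    if (length(vt_train) < 1L || length(vt_test) < 1L) {
      return(list(ok = FALSE,
                  reason = "no valid cancer type in train or test dataset"))
    }
    keep <- (ann$context == config$train_context &
               ann$cancer_type %in% vt_train) |
      (ann$context == config$test_context & ann$cancer_type %in% vt_test)
  } else {
    tr <- ann[ann$context == config$train_context, , drop = FALSE]
    vt <- valid_cancer_types(labels[tr$sample_id], tr$cancer_type)
    if (length(vt) < 2L) {
      return(list(ok = FALSE, reason = "fewer than 2 valid cancer types"))
    }
    if (!config$test_context %in% vt) {
      return(list(ok = FALSE,
                  reason = sprintf("held-out type '%s' not valid for this gene",
                                   config$test_context)))
    }
    keep <- ann$context == config$train_context &
      (ann$cancer_type %in% vt | ann$cancer_type == config$test_context)
  }
  list(ok = TRUE, annotations = ann[keep, , drop = FALSE])
}

#' Run a full generalization experiment
#'
#' Generates or loads the cohort, removes hypermutated samples (per
#' context), builds per-gene labels from point mutations plus
#' role-concordant CNV events, applies cancer-type validity and gene
#' retention, sweeps the regularization axis over all splits, applies both
#' selection strategies, and assembles generalization and comparison
#' tables. Deterministic given the configuration.
#'
#' @param config A [run_config()].
#' @return A `run_result` list: `sweeps` (all sweep rows), `selection`
#'   (per-gene selection report), `generalization` (per-measurement records
#'   at the best-selected parameter), `by_gene` aggregation, `wilcoxon`
#'   (strategy comparison test), `skipped` (gene, reason), `manifest`. When
#'   `config$output_dir` is set every table is also written as TSV plus a
#'   JSON manifest.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)

  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    expression <- cohort$expression
    ann <- cohort$annotations
    roles <- cohort$gene_roles
    calls <- threshold_cnv(cohort$cnv_values)
    point <- cohort$point_mutations
  } else {
    inputs <- read_cohort_inputs(config$paths, config$cnv_dialect,
                                 deep_only = config$deep_only)
    expression <- inputs$expression
    ann <- inputs$annotations
    roles <- tibble::as_tibble(config$gene_roles)
    calls <- cnv_calls(inputs$cnv, deep_only = config$deep_only)
    point <- vapply(roles$gene, function(g) {
      point_mutation_status(inputs$maf, inputs$samples, g)
    }, integer(nrow(ann)))
    rownames(point) <- inputs$samples
  }
  if (is.null(config$test_context)) {
    stop_config("test_context must be set")
  }

  # hypermutation filter, applied once per context before any per-gene work
  retained <- unlist(lapply(split(ann, ann$context), function(a) {
    hypermutation_filter(setNames(a$mutation_count, a$sample_id))$retained
  }), use.names = FALSE)
  n_removed <- nrow(ann) - length(retained)
  ann <- ann[ann$sample_id %in% retained, , drop = FALSE]
  expression <- expression[ann$sample_id, , drop = FALSE]

  genes <- config$genes %||% roles$gene
  design <- experiment_design(config$mode, config$train_context,
                              config$test_context, config$n_folds,
                              config$n_seeds)
  grid <- config$grid %||% if (config$model == "linear") default_c_grid() else NULL

  sweeps <- list(); reports <- list(); records <- list(); skipped <- list()
  for (g in genes) {
    role <- roles$role[roles$gene == g]
    labels <- label_samples(setNames(point[ann$sample_id, g], ann$sample_id),
                            calls[ann$sample_id, g], role, gene = g)
    res <- restrict_gene_cohort(ann, labels, config)
    if (!res$ok) {
      skipped[[g]] <- tibble::tibble(gene = g, reason = res$reason)
      next
    }
    sub <- res$annotations
    splits <- tryCatch(
      suppressWarnings(make_splits(sub, labels, design)),
      mutbench_data_error = function(e) NULL)
    if (is.null(splits)) {
      skipped[[g]] <- tibble::tibble(gene = g, reason = "split construction failed")
      next
    }
    block <- build_features(expression[sub$sample_id, , drop = FALSE],
                            setNames(sub$mutation_count, sub$sample_id),
                            labels)
    sw <- tryCatch({
      if (config$model == "linear") {
        run_linear_sweep(block, splits, grid, gene = g,
                         context = config$test_context)
      } else {
        run_mlp_sweep(block, splits, axis = config$axis, axis_values = grid,
                      hyperparameters = config$hyperparameters,
                      cancer_types = setNames(sub$cancer_type, sub$sample_id),
                      gene = g, context = config$test_context,
                      seed = config$seed)
      }
    }, mutbench_data_error = function(e) NULL)
    if (is.null(sw)) {
      skipped[[g]] <- tibble::tibble(gene = g, reason = "sweep failed (degenerate splits)")
      next
    }
    rep <- tryCatch(compare_strategies(sw),
                    mutbench_data_error = function(e) NULL)
    if (is.null(rep)) {
      skipped[[g]] <- tibble::tibble(gene = g, reason = "selection failed")
      next
    }
    sweeps[[g]] <- sw
    reports[[g]] <- rep
    records[[g]] <- generalization_records(sw, rep$best_param)
  }
  if (length(reports) == 0L) {
    stop_data("no gene could be analysed (see skipped reasons)")
  }

  selection <- dplyr::bind_rows(reports)
  generalization <- dplyr::bind_rows(records)
  result <- structure(list(
    sweeps = dplyr::bind_rows(sweeps),
    selection = selection,
    generalization = generalization,
    by_gene = aggregate_differences(generalization, by = "gene"),
    wilcoxon = strategy_wilcoxon(selection$difference),
    skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
      tibble::tibble(gene = character(), reason = character()),
    manifest = list(
      package_version = as.character(utils::packageVersion("mutbench")),
      config_hash = digest::digest(unclass(config)),
      mode = config$mode, model = config$model, axis = config$axis,
      seed = config$seed,
      n_samples = nrow(ann), n_hypermutated_removed = n_removed,
      n_genes_analysed = length(reports),
      n_genes_skipped = length(skipped))
  ), class = "run_result")

  if (!is.null(config$output_dir)) write_run_result(result, config)
  result
}

#' Write a run result's tables and manifest to a directory
#'
#' Emits `sweep.tsv`, `selection.tsv`, `generalization.tsv`,
#' `by_gene.tsv`, `skipped.tsv`, `manifest.json`, and the serialized
#' configuration `config.yaml`.
#'
#' @param result A `run_result` from [run_experiment()].
#' @param config The [run_config()] that produced it (for serialization).
#' @return Invisibly, the output directory.
#' @export
write_run_result <- function(result, config) {
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$sweeps, file.path(dir, "sweep.tsv"))
  readr::write_tsv(result$selection, file.path(dir, "selection.tsv"))
  readr::write_tsv(result$generalization, file.path(dir, "generalization.tsv"))
  readr::write_tsv(result$by_gene, file.path(dir, "by_gene.tsv"))
  readr::write_tsv(result$skipped, file.path(dir, "skipped.tsv"))
  manifest <- c(result$manifest, list(wilcoxon = result$wilcoxon))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- unclass(config)
  cfg$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
  cfg$output_dir <- NULL
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("run_result: %d gene(s) analysed, %d skipped\n",
              x$manifest$n_genes_analysed, x$manifest$n_genes_skipped))
  cat(sprintf("  median best-minus-smallest-good difference: %.4f (Wilcoxon p = %.3f)\n",
              median(x$selection$difference), x$wilcoxon$p_value))
  cat(sprintf("  median generalization difference (best model): %.4f\n",
              median(x$generalization$difference)))
  invisible(x)
}
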
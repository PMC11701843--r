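# Cohort construction: cancer-type validity, gene retention, modality
# intersection, and train/holdout/test split design.

#' Valid cancer types for a target gene
#'
#' A cancer type is valid for a gene when it has at least 15 mutated samples
#' and at least 5% mutated samples, ensuring enough positives to train a
#' classifier.
#'
#' @param labels Binary 0/1 vector of mutation-status labels.
#' @param types Character vector of per-sample cancer types, same length.
#' @param min_mutated Minimum mutated count (default 15).
#' @param min_proportion Minimum mutated proportion (default 0.05).
#' @return Character vector of valid cancer types (possibly empty).
#' @export
valid_cancer_types <- function(labels, types,
                               min_mutated = 15L, min_proportion = 0.05) {
  if (length(labels) == 0L) stop_data("empty cohort: no samples to assess")
  if (length(labels) != length(types)) {
    stop_data("labels and types are not aligned")
  }
  if (anyNA(types)) stop_data("every sample needs a cancer type")
  tab <- tapply(as.integer(labels), types, function(y) {
    c(mutated = sum(y), total = length(y))
  })
  ok <- vapply(tab, function(v) {
    v["mutated"] >= min_mutated && v["mutated"] / v["total"] >= min_proportion
  }, logical(1))
  sort(names(tab)[ok])
}

#' Gene-retention rule over valid-cancer-type sets
#'
#' In `cross_dataset` mode a gene is retained when it has at least one valid
#' cancer type in every dataset (one to train on, one to test on). In
#' `cancer_type_holdout` mode a gene needs at least two valid cancer types in
#' the single dataset: one to train on and one to hold out. Genes with no
#' valid types anywhere are dropped in both modes.
#'
#' @param valid_sets For `cross_dataset`: a named list (one element per
#'   dataset) of named lists mapping gene to its character vector of valid
#'   cancer types. For `cancer_type_holdout`: a single such gene-to-types
#'   list (or a one-element dataset list).
#' @param mode `"cross_dataset"` or `"cancer_type_holdout"`.
#' @return Character vector of retained gene symbols.
#' @export
retain_genes <- function(valid_sets, mode = c("cross_dataset", "cancer_type_holdout")) {
  mode <- match.arg(mode)
  if (mode == "cross_dataset") {
    if (length(valid_sets) < 2L) {
      stop_config("cross_dataset retention needs valid-type sets for >= 2 datasets")
    }
    genes <- unique(unlist(lapply(valid_sets, names)))
    keep <- vapply(genes, function(g) {
      all(vapply(valid_sets, function(ds) length(ds[[g]]) >= 1L, logical(1)))
    }, logical(1))
  } else {
    if (is.list(valid_sets) && length(valid_sets) == 1L &&
        is.list(valid_sets[[1L]]) && !is.character(valid_sets[[1L]])) {
      valid_sets <- valid_sets[[1L]]
    }
    genes <- names(valid_sets)
    keep <- vapply(genes, function(g) length(valid_sets[[g]]) >= 2L, logical(1))
  }
  sort(genes[keep])
}

#' Intersect data modalities into an aligned cohort
#'
#' Restricts samples to those present in every supplied modality and, when
#' several expression feature sets are supplied (cross-dataset mode), genes
#' to their intersection. Output ordering is deterministic: samples and genes
#' sorted lexicographically.
#'
#' @param expression Samples x genes matrix (or a named list of such matrices
#'   from different datasets, whose gene sets are intersected).
#' @param annotations Data frame with a `sample_id` column.
#' @param ... Further named per-sample tables to align: matrices with sample
#'   rownames or vectors with sample names.
#' @return A list with `expression` (single matrix or list, rows/genes
#'   aligned), `annotations`, and the aligned extra tables.
#' @export
intersect_modalities <- function(expression, annotations, ...) {
  extras <- list(...)
  expr_list <- if (is.list(expression) && !is.matrix(expression)) expression else list(expression)
  sample_sets <- c(
    list(unlist(lapply(expr_list, rownames), use.names = FALSE)),
    list(annotations$sample_id),
    lapply(extras, function(x) if (is.matrix(x)) rownames(x) else names(x))
  )
  samples <- sort(Reduce(intersect, sample_sets))
  if (length(samples) == 0L) stop_data("modalities share no samples")
  genes <- sort(Reduce(intersect, lapply(expr_list, colnames)))
  if (length(genes) == 0L) stop_data("expression matrices share no genes")
  expr_list <- lapply(expr_list, function(m) {
    m[samples[samples %in% rownames(m)], genes, drop = FALSE]
  })
  out <- list(
    expression = if (is.list(expression) && !is.matrix(expression)) expr_list else expr_list[[1L]],
    annotations = annotations[match(samples, annotations$sample_id), , drop = FALSE]
  )
  aligned <- lapply(extras, function(x) {
    if (is.matrix(x)) x[samples, , drop = FALSE] else x[samples]
  })
  c(out, aligned)
}

#' Experiment design for a generalization benchmark
#'
#' @param mode `"cross_dataset"` (train on one dataset, test on the other) or
#'   `"cancer_type_holdout"` (train on all but one cancer type, test on it).
#' @param train_context Dataset label to train on.
#' @param test_context Dataset label (cross_dataset) or held-out cancer type
#'   (cancer_type_holdout) used as the fixed test set.
#' @param n_folds Cross-validation folds (default 4; each fold serves once as
#'   the 25% holdout).
#' @param n_seeds Random seeds for refolding (default 2; 4 x 2 = 8
#'   measurements per parameter).
#' @param train_fraction Fraction of the training context used for fitting in
#'   each split (default 0.75 = 1 - 1/n_folds).
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(mode = c("cross_dataset", "cancer_type_holdout"),
                              train_context, test_context,
                              n_folds = 4L, n_seeds = 2L,
                              train_fraction = 1 - 1 / n_folds) {
  mode <- match.arg(mode)
  if (!is_count(n_folds) || n_folds < 2L) stop_config("n_folds must be >= 2")
  if (!is_count(n_seeds)) stop_config("n_seeds must be a positive count")
  if (abs(train_fraction - (1 - 1 / n_folds)) > 1e-8) {
    stop_config("train_fraction must equal 1 - 1/n_folds (folds partition the holdout)")
  }
  structure(list(mode = mode, train_context = train_context,
                 test_context = test_context, n_folds = as.integer(n_folds),
                 n_seeds = as.integer(n_seeds),
                 train_fraction = train_fraction),
            class = "experiment_design")
}

#' Build train/holdout/test split assignments
#'
#' The test set is the entire held-out context (the other dataset, or the
#' held-out cancer type) and is identical across folds and seeds. The
#' remaining samples are partitioned, per seed, into `n_folds` folds
#' stratified jointly by (cancer type, label); each fold serves once as the
#' holdout set, the rest as the training set. Strata smaller than the fold
#' count are downgraded to label-only stratification with a warning. Sample
#' IDs are sorted before any seeded shuffling, so the seeds fully determine
#' the assignment.
#'
#' @param annotations Data frame with `sample_id`, `cancer_type`, and either
#'   `context` (cross_dataset) or only cancer types (cancer_type_holdout).
#' @param labels Named 0/1 vector over (at least) the training-context
#'   samples.
#' @param design An [experiment_design()].
#' @return A `split_assignment` list: `test_ids`, and `folds`, a tibble with
#'   columns `seed`, `fold`, `sample_id` assigning every non-test sample to
#'   one fold per seed.
#' @export
make_splits <- function(annotations, labels, design) {
  if (design$mode == "cross_dataset") {
    in_test <- annotations$context == design$test_context
    in_train <- annotations$context == design$train_context
  } else {
    in_test <- annotations$cancer_type == design$test_context
    in_train <- !in_test
  }
  if (!any(in_test)) stop_data("test context '%s' has no samples", design$test_context)
  if (!any(in_train)) stop_data("train context '%s' has no samples", design$train_context)
  test_ids <- sort(annotations$sample_id[in_test])
  pool <- annotations[in_train, , drop = FALSE]
  pool <- pool[order(pool$sample_id), , drop = FALSE]
  y <- labels[pool$sample_id]
  if (anyNA(y)) stop_data("labels missing for some training-context samples")

  strata <- paste(pool$cancer_type, y, sep = "|")
  small <- names(which(table(strata) < design$n_folds))
  if (length(small) > 0) {
    warning(sprintf(
      "%d stratum/strata smaller than n_folds; downgrading to label-only stratification for: %s",
      length(small), paste(small, collapse = ", ")), call. = FALSE)
    strata[strata %in% small] <- paste("label-only", y[strata %in% small], sep = "|")
  }

  folds <- do.call(rbind, lapply(seq_len(design$n_seeds), function(s) {
    assign <- integer(nrow(pool))
    with_seed(1000L * design$n_folds + s, {
      for (st in unique(strata)) {
        idx <- which(strata == st)
        idx <- idx[sample.int(length(idx))]
        assign[idx] <- rep_len(seq_len(design$n_folds), length(idx))
      }
    })
    data.frame(seed = s, fold = assign, sample_id = pool$sample_id,
               stringsAsFactors = FALSE)
  }))
  structure(list(test_ids = test_ids, folds = tibble::as_tibble(folds),
                 design = design),
            class = "split_assignment")
}

#' Train and holdout sample IDs for one (seed, fold) split
#'
#' @param splits A `split_assignment` from [make_splits()].
#' @param seed,fold Which refolding seed and which fold serves as holdout.
#' @return List with `train` and `holdout` character vectors.
#' @export
split_members <- function(splits, seed, fold) {
  f <- splits$folds[splits$folds$seed == seed, , drop = FALSE]
  if (nrow(f) == 0L) stop_config("no such seed %s in split assignment", seed)
  list(train = f$sample_id[f$fold != fold],
       holdout = f$sample_id[f$fold == fold])
}
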
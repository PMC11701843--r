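# File adapters: writers that emit the on-disk dialects the pipeline reads
# (expression TSV, MAF-like mutation TSV, CNV CSV in either dialect,
# annotation TSV), and the readers that load them back into the shared data
# model. Writers and readers are inverse on synthetic cohorts.

#' Write a synthetic cohort to disk in the pipeline's input dialects
#'
#' Emits `expression.tsv` (samples x genes), `mutations.tsv` (MAF-like long
#' table: sample_id, gene, variant_classification — one non-silent row per
#' counted mutation, point mutations in target genes included, plus a
#' sprinkling of silent rows that readers must ignore), `cnv.csv`
#' (continuous CCLE-style log-scale values), and `annotations.tsv`
#' (sample_id, context, cancer_type).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param silent_fraction Extra silent variant rows, as a fraction of the
#'   non-silent row count, written to exercise the non-silent filter.
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir, silent_fraction = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- cohort$annotations
  paths <- c(expression = file.path(dir, "expression.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             cnv = file.path(dir, "cnv.csv"),
             annotations = file.path(dir, "annotations.tsv"))

  expr_df <- data.frame(sample_id = rownames(cohort$expression),
                        cohort$expression, check.names = FALSE)
  readr::write_tsv(expr_df, paths["expression"])

  maf <- with_seed(cohort$truth$config$seed + 2L, {
    rows <- lapply(seq_len(nrow(ann)), function(i) {
      sid <- ann$sample_id[i]
      target_hits <- colnames(cohort$point_mutations)[
        cohort$point_mutations[sid, ] == 1L]
      n_bg <- ann$mutation_count[i] - length(target_hits)
      genes <- c(target_hits,
                 if (n_bg > 0) sprintf("BG%05d", sample.int(99999L, n_bg)))
      data.frame(sample_id = sid, gene = genes,
                 variant_classification = sample(nonsilent_classes(),
                                                 length(genes), replace = TRUE))
    })
    maf <- do.call(rbind, rows)
    n_silent <- round(silent_fraction * nrow(maf))
    if (n_silent > 0) {
      silent <- data.frame(
        sample_id = sample(ann$sample_id, n_silent, replace = TRUE),
        gene = c(sample(colnames(cohort$point_mutations), n_silent, replace = TRUE)),
        variant_classification = sample(c("Silent", "3'UTR", "Intron"),
                                        n_silent, replace = TRUE))
      maf <- rbind(maf, silent)
    }
    maf[order(maf$sample_id, maf$gene), , drop = FALSE]
  })
  readr::write_tsv(maf, paths["mutations"])

  cnv_df <- data.frame(sample_id = rownames(cohort$cnv_values),
                       cohort$cnv_values, check.names = FALSE)
  readr::write_csv(cnv_df, paths["cnv"])

  readr::write_tsv(ann[, c("sample_id", "context", "cancer_type")],
                   paths["annotations"])
  invisible(paths)
}

read_delim_quiet <- function(path, delim) {
  if (!file.exists(path)) stop_data("input file not found: %s", path)
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

delim_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read an expression matrix from TSV/CSV
#'
#' @param path File with one identifier column (first column) and numeric
#'   feature columns; comma- or tab-separated by extension.
#' @param orientation `"samples_by_genes"` (rows are samples, the default)
#'   or `"genes_by_samples"` (transposed on read).
#' @return Numeric matrix, samples x genes, with identifier dimnames.
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes", "genes_by_samples")) {
  orientation <- match.arg(orientation)
  df <- read_delim_quiet(path, delim_for(path))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop_data("duplicate identifiers in %s", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "genes_by_samples") m <- t(m)
  storage.mode(m) <- "double"
  m
}

#' Read a MAF-like mutation table
#'
#' @param path Tab- or comma-separated file.
#' @param columns Column mapping from [maf_columns()]; all mapped columns
#'   must be present.
#' @return A tibble with the mapped columns.
#' @export
read_maf <- function(path, columns = maf_columns()) {
  df <- read_delim_quiet(path, delim_for(path))
  check_maf(df, columns)
}

#' Read a copy-number table in either dialect
#'
#' @param path Samples x genes table; first column is the sample ID (or the
#'   gene ID with `orientation = "genes_by_samples"`).
#' @param dialect `"continuous"` (CCLE-style log-scale values) or
#'   `"thresholded"` (GISTIC-style integer calls in -2..2).
#' @param orientation As in [read_expression()].
#' @return Numeric matrix with attribute `dialect`.
#' @export
read_cnv <- function(path, dialect = c("continuous", "thresholded"),
                     orientation = c("samples_by_genes", "genes_by_samples")) {
  dialect <- match.arg(dialect)
  m <- read_expression(path, orientation = match.arg(orientation))
  attr(m, "dialect") <- dialect
  m
}

#' Turn a copy-number matrix into gain/loss/neutral calls
#'
#' Routes continuous-dialect matrices through [threshold_cnv()] and
#' thresholded-dialect matrices through [calls_from_thresholded()].
#'
#' @param cnv Matrix from [read_cnv()] (or any matrix plus an explicit
#'   `dialect`).
#' @param dialect Overrides the matrix's `dialect` attribute.
#' @param deep_only Passed to [calls_from_thresholded()].
#' @return A `cnv_calls` matrix.
#' @export
cnv_calls <- function(cnv, dialect = attr(cnv, "dialect"), deep_only = TRUE) {
  if (is.null(dialect)) stop_config("CNV dialect not declared")
  switch(dialect,
         continuous = threshold_cnv(cnv),
         thresholded = calls_from_thresholded(cnv, deep_only = deep_only),
         stop_config("unknown CNV dialect '%s'", dialect))
}

#' Read the sample annotation table
#'
#' @param path TSV/CSV with columns `sample_id`, `context`, `cancer_type`.
#' @return A tibble; duplicate sample IDs are an error.
#' @export
read_annotations <- function(path) {
  df <- read_delim_quiet(path, delim_for(path))
  need <- c("sample_id", "context", "cancer_type")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_data("annotation file missing column(s): %s",
              paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop_data("duplicate sample IDs in %s", path)
  }
  df
}

#' Load and align the pipeline's file-based inputs
#'
#' Reads expression, MAF-like mutations, CNV, and annotations; computes
#' per-sample non-silent burden from the MAF; intersects samples across
#' modalities (sorted identifiers) and returns the shared in-memory cohort
#' inputs.
#'
#' @param paths Named list/vector with entries `expression`, `mutations`,
#'   `cnv`, `annotations`.
#' @param cnv_dialect,expression_orientation,deep_only,columns Dialect
#'   configuration for the individual readers.
#' @return A list: `expression` (matrix), `annotations` (tibble incl.
#'   `mutation_count`), `maf` (tibble), `cnv` (matrix with dialect), and
#'   `samples`.
#' @export
read_cohort_inputs <- function(paths,
                               cnv_dialect = c("continuous", "thresholded"),
                               expression_orientation = "samples_by_genes",
                               deep_only = TRUE,
                               columns = maf_columns()) {
  cnv_dialect <- match.arg(cnv_dialect)
  expr <- read_expression(paths[["expression"]], expression_orientation)
  maf <- read_maf(paths[["mutations"]], columns)
  cnv <- read_cnv(paths[["cnv"]], cnv_dialect)
  ann <- read_annotations(paths[["annotations"]])
  samples <- sort(Reduce(intersect, list(rownames(expr), ann$sample_id,
                                         rownames(cnv))))
  if (length(samples) == 0L) stop_data("modalities share no samples")
  ann <- ann[match(samples, ann$sample_id), , drop = FALSE]
  ann$mutation_count <- mutation_burden(maf, samples, columns = columns)
  cnv_sub <- cnv[samples, , drop = FALSE]
  attr(cnv_sub, "dialect") <- cnv_dialect
  list(expression = expr[samples, , drop = FALSE],
       annotations = ann,
       maf = maf[maf[[columns$sample]] %in% samples, , drop = FALSE],
       cnv = cnv_sub,
       samples = samples)
}
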
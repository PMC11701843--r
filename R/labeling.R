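#' Variant classes counted as non-silent
#'
#' The default set of MAF variant classifications treated as non-silent when
#' building mutation-status labels and per-sample mutation-burden counts:
#' missense, nonsense, frameshift, splice-site, nonstop, translation start
#' site and in-frame indels.
#'
#' @return Character vector of variant classification strings.
#' @export
nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins",
    "Splice_Site", "Nonstop_Mutation", "Translation_Start_Site",
    "In_Frame_Del", "In_Frame_Ins")
}

#' Threshold continuous copy-number values into gain/loss/neutral calls
#'
#' Continuous copy-number values are expected on a log2 scale where the
#' diploid value sits near 1.0 (the log2(relative copy number + 1)
#' convention). A value below `lower` (default log2(3/2), about 0.585) is a
#' full copy loss; a value above `upper` (default log2(5/2), about 1.322) is
#' a full copy gain; everything in between is neutral. The defaults only make
#' sense on that scale.
#'
#' @param values Numeric matrix or data frame, samples x genes, finite.
#' @param lower,upper Loss / gain thresholds on the same scale as `values`.
#' @return A `cnv_calls` object: a character matrix with entries in
#'   `{"loss","neutral","gain"}` and attribute `dialect = "continuous"`.
#' @export
threshold_cnv <- function(values, lower = log2(3 / 2), upper = log2(5 / 2)) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_data("non-finite CNV value at sample '%s', gene '%s'",
              rownames(values)[bad[1L]] %||% bad[1L],
              colnames(values)[bad[2L]] %||% bad[2L])
  }
  if (lower >= upper) stop_config("lower threshold must be below upper")
  calls <- matrix("neutral", nrow(values), ncol(values),
                  dimnames = dimnames(values))
  calls[values < lower] <- "loss"
  calls[values > upper] <- "gain"
  structure(calls, class = c("cnv_calls", class(calls)),
            dialect = "continuous")
}

#' Convert thresholded integer copy-number calls into gain/loss/neutral
#'
#' Accepts GISTIC-style integer calls in \{-2, -1, 0, 1, 2\}. With
#' `deep_only = TRUE` (the default) only deep events count: gain iff +2 and
#' loss iff -2. With `deep_only = FALSE` any directional call counts: gain
#' iff > 0, loss iff < 0.
#'
#' @param calls Integer matrix or data frame, samples x genes.
#' @param deep_only Whether only deep (+/-2) events count as gain/loss.
#' @return A `cnv_calls` character matrix with attribute
#'   `dialect = "thresholded"`.
#' @export
calls_from_thresholded <- function(calls, deep_only = TRUE) {
  calls <- as.matrix(calls)
  ok <- is.finite(calls) & calls %in% c(-2L, -1L, 0L, 1L, 2L)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_data("thresholded CNV call outside {-2..2} at sample '%s', gene '%s'",
              rownames(calls)[bad[1L]] %||% bad[1L],
              colnames(calls)[bad[2L]] %||% bad[2L])
  }
  out <- matrix("neutral", nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  if (deep_only) {
    out[calls == 2] <- "gain"
    out[calls == -2] <- "loss"
  } else {
    out[calls > 0] <- "gain"
    out[calls < 0] <- "loss"
  }
  structure(out, class = c("cnv_calls", class(out)), dialect = "thresholded")
}

#' Remove hypermutated samples by the mean + 2 SD rule
#'
#' A sample is hypermutated when its non-silent somatic mutation count is two
#' or more sample standard deviations (n - 1 denominator) above the cohort
#' mean; such samples are removed before any per-gene labeling. When the
#' standard deviation is exactly 0 no outliers can exist and all samples are
#' retained. The filter is applied once per dataset; re-applying it to its
#' own output can remove further samples and is deliberately not done.
#'
#' @param burdens Named non-negative numeric vector of per-sample non-silent
#'   mutation counts, length >= 2.
#' @return A list with `retained` (names, or indices when unnamed),
#'   `removed`, and the numeric `threshold` = mean + 2 SD actually used.
#' @export
hypermutation_filter <- function(burdens) {
  if (length(burdens) < 2L) {
    stop_data("hypermutation filter needs at least 2 samples (SD undefined)")
  }
  if (anyNA(burdens) || any(burdens < 0)) {
    stop_data("mutation-burden counts must be non-negative and non-missing")
  }
  ids <- names(burdens) %||% seq_along(burdens)
  s <- sd(burdens)
  threshold <- mean(burdens) + 2 * s
  if (s == 0) {
    keep <- rep(TRUE, length(burdens))
  } else {
    keep <- burdens < threshold
  }
  list(retained = ids[keep], removed = ids[!keep], threshold = threshold)
}

#' Build binary mutation-status labels for one target gene
#'
#' A sample is labeled positive when it carries a non-silent point mutation
#' in the target gene, or a role-concordant copy-number event: a copy gain
#' when the gene is an oncogene, a copy loss when it is a tumor suppressor.
#' All remaining samples are negative.
#'
#' @param point_mutations Named binary vector (1 = non-silent mutation in the
#'   target gene) over samples.
#' @param cnv_calls Character vector of calls in `{"loss","neutral","gain"}`
#'   for the target gene, aligned to the same samples (or a `cnv_calls`
#'   matrix from which the `gene` column is taken).
#' @param role `"oncogene"` or `"tumor_suppressor"`.
#' @param gene Gene symbol, used when `cnv_calls` is a matrix and for the
#'   result's metadata.
#' @return An integer 0/1 vector named by sample, with attributes `gene` and
#'   `role`.
#' @export
label_samples <- function(point_mutations, cnv_calls, role,
                          gene = attr(point_mutations, "gene") %||% "target") {
  if (!role %in% c("oncogene", "tumor_suppressor")) {
    stop_config("unknown gene role '%s' (expected oncogene or tumor_suppressor)",
                as.character(role))
  }
  if (is.matrix(cnv_calls)) {
    if (!gene %in% colnames(cnv_calls)) {
      stop_data("gene '%s' absent from CNV call table", gene)
    }
    cnv_calls <- cnv_calls[, gene]
  }
  if (length(point_mutations) != length(cnv_calls)) {
    stop_data("point mutation and CNV vectors are not aligned")
  }
  if (!all(cnv_calls %in% c("loss", "neutral", "gain"))) {
    stop_data("CNV calls must be in {loss, neutral, gain}")
  }
  concordant <- if (role == "oncogene") cnv_calls == "gain" else cnv_calls == "loss"
  labels <- as.integer(point_mutations == 1 | concordant)
  names(labels) <- names(point_mutations)
  structure(labels, gene = gene, role = role)
}

#' Per-sample non-silent mutation burden from a MAF-like table
#'
#' Counts non-silent variant rows per sample. Samples present in `samples`
#' but absent from the table get a count of 0.
#'
#' @param maf Data frame with at least sample and variant classification
#'   columns (default names `sample_id`, `variant_classification`).
#' @param samples Character vector of sample IDs to report counts for.
#' @param classes Variant classes counted as non-silent
#'   (default [nonsilent_classes()]).
#' @param columns Named list mapping the roles `sample`, `gene`,
#'   `classification` to the column names in `maf`.
#' @return Named integer vector of counts over `samples`.
#' @export
mutation_burden <- function(maf, samples,
                            classes = nonsilent_classes(),
                            columns = maf_columns()) {
  maf <- check_maf(maf, columns)
  ns <- maf[maf[[columns$classification]] %in% classes, , drop = FALSE]
  counts <- table(factor(ns[[columns$sample]], levels = samples))
  setNames(as.integer(counts), samples)
}

#' Per-sample point-mutation indicator for one gene from a MAF-like table
#'
#' @inheritParams mutation_burden
#' @param gene Target gene symbol.
#' @return Named 0/1 integer vector over `samples` with attribute `gene`.
#' @export
point_mutation_status <- function(maf, samples, gene,
                                  classes = nonsilent_classes(),
                                  columns = maf_columns()) {
  maf <- check_maf(maf, columns)
  hit <- maf[[columns$gene]] == gene &
    maf[[columns$classification]] %in% classes
  mutated <- unique(maf[[columns$sample]][hit])
  structure(setNames(as.integer(samples %in% mutated), samples), gene = gene)
}

#' Default column mapping for MAF-like mutation tables
#'
#' @param sample,gene,classification Column names in the input table.
#' @return Named list used by the MAF readers.
#' @export
maf_columns <- function(sample = "sample_id", gene = "gene",
                        classification = "variant_classification") {
  list(sample = sample, gene = gene, classification = classification)
}

check_maf <- function(maf, columns) {
  missing <- setdiff(unlist(columns), names(maf))
  if (length(missing) > 0) {
    stop_data("MAF-like table is missing required column(s): %s",
              paste(missing, collapse = ", "))
  }
  maf
}
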
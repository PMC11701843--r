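#' Area under the precision-recall curve (average precision)
#'
#' Computes the area under the precision-recall curve with the step-wise
#' average-precision estimator: the sum over distinct score thresholds of the
#' recall increment times the precision at that threshold. Tied scores are
#' handled by moving the operating point over whole tie groups, so the value
#' is invariant to any strictly monotone transform of the scores.
#'
#' The average-precision estimator is used rather than trapezoidal
#' interpolation because linear interpolation between PR points is a known
#' optimistic bias for precision-recall curves.
#'
#' @param scores Numeric vector of continuous classifier scores (higher means
#'   more likely positive).
#' @param labels Binary vector (0/1 or logical) of the same length. Both
#'   classes must be present.
#' @return A single number in \[0, 1\].
#' @examples
#' aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)) # perfect ranking -> 1
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop_data("scores (%d) and labels (%d) differ in length",
              length(scores), length(labels))
  }
  if (anyNA(scores) || anyNA(labels)) stop_data("NA in scores or labels")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || n_pos == length(labels)) {
    stop_data("AUPR undefined: labels contain a single class")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  # close each tie group at its last element
  grp_end <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[grp_end]
  np <- seq_along(y)[grp_end]
  precision <- tp / np
  recall_inc <- diff(c(0L, tp)) / n_pos
  sum(recall_inc * precision)
}

#' Baseline-corrected AUPR
#'
#' Subtracts the positive-class prevalence of the evaluation set from a raw
#' AUPR. Prevalence is the expected AUPR of a random (or constant-score)
#' classifier, so a corrected value of 0 marks an uninformative model and the
#' corrected value lies in \[-prevalence, 1 - prevalence\].
#'
#' @param raw Raw AUPR value.
#' @param prevalence Positive fraction of the evaluation set, strictly
#'   inside (0, 1).
#' @return Corrected AUPR.
#' @export
corrected_aupr <- function(raw, prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop_data("prevalence must lie strictly inside (0, 1)")
  }
  raw - prevalence
}

#' Generalization difference between holdout and test evaluations
#'
#' Corrected holdout AUPR minus corrected test AUPR, each term corrected with
#' its own evaluation set's prevalence. Positive values indicate poor
#' generalization (the model does better in its training context than in the
#' held-out context); zero or negative values indicate good generalization.
#'
#' @param holdout_aupr,holdout_prevalence Raw AUPR and prevalence on the
#'   within-context holdout set.
#' @param test_aupr,test_prevalence Raw AUPR and prevalence on the held-out
#'   context.
#' @return The signed difference in corrected AUPR units.
#' @export
generalization_difference <- function(holdout_aupr, holdout_prevalence,
                                      test_aupr, test_prevalence) {
  corrected_aupr(holdout_aupr, holdout_prevalence) -
    corrected_aupr(test_aupr, test_prevalence)
}

#' Percentile bootstrap confidence interval for AUPR
#'
#' Resamples evaluation samples (not cross-validation measurements) with
#' replacement and returns a percentile interval of the AUPR. Resamples that
#' lose one of the two classes are redrawn, with a cap of `10 * B` total
#' redraws.
#'
#' @param scores,labels As in [aupr()].
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @return A named numeric vector with elements `lower`, `upper` and
#'   `estimate` (the AUPR on the original sample).
#' @export
bootstrap_ci <- function(scores, labels, B = 1000L, level = 0.95) {
  labels <- as.integer(labels)
  point <- aupr(scores, labels)
  n <- length(scores)
  stats <- numeric(B)
  draws <- 0L
  kept <- 0L
  while (kept < B) {
    if (draws >= 10L * B) {
      stop_data(paste0(
        "bootstrap resampling kept losing a class after ", draws,
        " draws; use a larger evaluation set"))
    }
    idx <- sample.int(n, n, replace = TRUE)
    draws <- draws + 1L
    yb <- labels[idx]
    if (all(yb == yb[1L])) next
    kept <- kept + 1L
    stats[kept] <- aupr(scores[idx], yb)
  }
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stats, c(alpha, 1 - alpha), type = 7))
  c(lower = ci[1L], upper = ci[2L], estimate = point)
}

#' Rank regularization-axis values by per-gene test performance
#'
#' For each gene, ranks the axis values (for example hidden-layer sizes) by
#' test AUPR, rank 1 being the best, averaging ranks over ties. Then, for each
#' axis value, counts how many genes placed it above, below, or exactly at the
#' median rank of the 1..k scale (5.5 when k = 10).
#'
#' @param test_aupr A data frame with columns `gene`, `param` and `aupr`
#'   (test-set AUPR; corrected or raw — ranks are invariant to the per-gene
#'   baseline shift).
#' @return A list with `ranks` (tibble: gene, param, rank) and `counts`
#'   (tibble: param, above_median, below_median, at_median) plus the scalar
#'   `median_rank`. Genes missing any axis value are excluded with a message.
#' @export
rank_axis <- function(test_aupr) {
  stopifnot(all(c("gene", "param", "aupr") %in% names(test_aupr)))
  params <- sort(unique(test_aupr$param))
  k <- length(params)
  complete <- test_aupr |>
    dplyr::distinct(.data$gene, .data$param, .keep_all = TRUE) |>
    dplyr::group_by(.data$gene) |>
    dplyr::filter(dplyr::n() == k) |>
    dplyr::ungroup()
  dropped <- setdiff(unique(test_aupr$gene), unique(complete$gene))
  if (length(dropped) > 0) {
    message("rank_axis: excluding ", length(dropped),
            " gene(s) with missing axis values: ",
            paste(dropped, collapse = ", "))
  }
  if (nrow(complete) == 0) stop_data("no gene has all axis values evaluated")
  ranks <- complete |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(rank = rank(-.data$aupr, ties.method = "average")) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "param", "rank")
  med <- (k + 1) / 2
  counts <- ranks |>
    dplyr::group_by(param = .data$param) |>
    dplyr::summarise(
      above_median = sum(.data$rank > med),
      below_median = sum(.data$rank < med),
      at_median = sum(.data$rank == med),
      .groups = "drop"
    )
  list(ranks = ranks, counts = counts, median_rank = med)
}

#' Aggregate generalization differences by gene or by cancer type
#'
#' Summarises a table of generalization differences per group with the
#' median, quartiles and count, ordered by median from highest (worst
#' generalization) to lowest.
#'
#' @param records A data frame with a `difference` column and the grouping
#'   column named by `by`.
#' @param by Grouping column name, typically `"gene"` or `"cancer_type"`.
#' @return A tibble with columns `by`-group, `median`, `q1`, `q3`, `n`,
#'   sorted by descending median.
#' @export
aggregate_differences <- function(records, by = "gene") {
  if (!by %in% names(records)) stop_config("no column '%s' in records", by)
  if (!"difference" %in% names(records)) {
    stop_config("records must have a 'difference' column")
  }
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      median = median(.data$difference),
      q1 = unname(quantile(.data$difference, 0.25)),
      q3 = unname(quantile(.data$difference, 0.75)),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$median))
}
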
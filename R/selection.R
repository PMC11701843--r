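# Model selection: "best" (top mean holdout AUPR) versus "smallest good"
# (most regularized model within one standard error of the best), and their
# comparison statistic. Selection reads holdout measurements only; test-set
# values enter only after the parameters have been chosen.

#' Regularization orientation of a sweep axis
#'
#' Registry of what "more regularized" means per axis: a smaller C, a
#' smaller hidden-layer size, a larger dropout proportion, or a larger
#' weight decay.
#'
#' @param axis Axis name: `"C"`, `"hidden_size"`, `"dropout"`,
#'   `"weight_decay"`.
#' @return `+1` when larger parameter values are more regularized, `-1` when
#'   smaller values are.
#' @export
axis_orientation <- function(axis) {
  switch(axis,
    C = -1, hidden_size = -1,
    dropout = +1, weight_decay = +1,
    stop_config("unknown regularization axis '%s'", axis))
}

#' Summarise holdout performance per regularization value
#'
#' Takes the mean over the (by default 8: 4 folds x 2 seeds) holdout
#' measurements per parameter as the single per-parameter performance value,
#' with the standard error SE = sample SD / sqrt(m).
#'
#' @param sweep A `sweep_result` tibble (one gene).
#' @param role Which evaluation role to summarise (default `"holdout"`).
#' @return A `parameter_summary` tibble: `param`, `mean_aupr`, `se`, `m`,
#'   with attribute `axis`.
#' @export
summarize_parameters <- function(sweep, role = "holdout") {
  rows <- sweep[sweep$role == role & !is.na(sweep$aupr), , drop = FALSE]
  if (nrow(rows) == 0L) stop_data("no %s measurements to summarise", role)
  axis <- unique(rows$axis)
  if (length(axis) != 1L) stop_data("mixed axes in one sweep summary")
  out <- rows |>
    dplyr::group_by(param = .data$param) |>
    dplyr::summarise(mean_aupr = mean(.data$aupr),
                     se = sd(.data$aupr) / sqrt(dplyr::n()),
                     m = dplyr::n(), .groups = "drop")
  attr(out, "axis") <- axis
  class(out) <- c("parameter_summary", class(out))
  out
}

#' Select the best model: top mean holdout performance
#'
#' Ties are broken toward the more regularized parameter.
#'
#' @param summary A [summarize_parameters()] table.
#' @param axis Axis name (defaults to the summary's axis attribute).
#' @return The selected parameter value.
#' @export
select_best <- function(summary, axis = attr(summary, "axis")) {
  if (is.null(summary) || nrow(summary) == 0L) stop_data("empty parameter summary")
  orient <- axis_orientation(axis)
  best <- max(summary$mean_aupr)
  cand <- summary$param[summary$mean_aupr == best]
  if (orient < 0) min(cand) else max(cand)
}

#' Select the smallest good model: one-standard-error rule
#'
#' Among parameters whose mean holdout performance is within one standard
#' error of the best mean (SE of the best parameter's measurements), returns
#' the most regularized one — the glmnet `lambda.1se` heuristic generalized
#' to any regularization axis via [axis_orientation()]. With SE = 0 only
#' parameters matching the best mean qualify.
#'
#' @inheritParams select_best
#' @return The selected parameter value.
#' @export
select_smallest_good <- function(summary, axis = attr(summary, "axis")) {
  if (is.null(summary) || nrow(summary) == 0L) stop_data("empty parameter summary")
  orient <- axis_orientation(axis)
  best_param <- select_best(summary, axis)
  i_best <- match(best_param, summary$param)
  if (summary$m[i_best] < 2L) {
    stop_data("standard error undefined: best parameter has fewer than 2 measurements")
  }
  threshold <- summary$mean_aupr[i_best] - summary$se[i_best]
  qualifying <- summary$param[summary$mean_aupr >= threshold]
  if (orient < 0) min(qualifying) else max(qualifying)
}

#' Compare best and smallest-good selection on one sweep
#'
#' Applies both selectors to the holdout summaries, then evaluates each
#' selected parameter as the mean test AUPR over the same measurement
#' replicates, and reports the difference best minus smallest good (raw
#' AUPR; both strategies score the same evaluation set, so baseline
#' correction cancels and is not applied). Positive differences favor the
#' best model; the difference is exactly 0 whenever the same parameter wins
#' both criteria.
#'
#' @param sweep A `sweep_result` for one gene/context.
#' @return A one-row `selection_report` tibble: `gene`, `context`, `axis`,
#'   `best_param`, `smallest_good_param`, `best_holdout_aupr`,
#'   `smallest_good_holdout_aupr`, `best_test_aupr`,
#'   `smallest_good_test_aupr`, `difference`.
#' @export
compare_strategies <- function(sweep) {
  summary <- summarize_parameters(sweep, role = "holdout")
  axis <- attr(summary, "axis")
  best <- select_best(summary, axis)
  small <- select_smallest_good(summary, axis)
  test_mean <- function(param) {
    rows <- sweep[sweep$role == "test" & sweep$param == param &
                    !is.na(sweep$aupr), , drop = FALSE]
    if (nrow(rows) == 0L) stop_data("no test measurements for parameter %s", param)
    mean(rows$aupr)
  }
  best_test <- test_mean(best)
  small_test <- if (identical(small, best)) best_test else test_mean(small)
  tibble::tibble(
    gene = unique(sweep$gene), context = unique(sweep$context), axis = axis,
    best_param = best, smallest_good_param = small,
    best_holdout_aupr = summary$mean_aupr[match(best, summary$param)],
    smallest_good_holdout_aupr = summary$mean_aupr[match(small, summary$param)],
    best_test_aupr = best_test, smallest_good_test_aupr = small_test,
    difference = if (identical(small, best)) 0 else best_test - small_test
  )
}

#' Wilcoxon signed-rank test on per-gene strategy differences
#'
#' Two-sided signed-rank test of whether the distribution of best-minus-
#' smallest-good differences is centered at zero. Exact zeros are dropped
#' before testing (the classic convention); when every difference is zero
#' the test is degenerate and p = 1 is reported with a flag.
#'
#' @param differences Numeric vector of per-gene differences.
#' @return List with `statistic`, `p_value`, `n_nonzero`, `degenerate`.
#' @export
strategy_wilcoxon <- function(differences) {
  if (anyNA(differences)) stop_data("differences contain NA")
  nz <- differences[differences != 0]
  if (length(nz) == 0L) {
    return(list(statistic = NA_real_, p_value = 1, n_nonzero = 0L,
                degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(nz, mu = 0, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = length(nz), degenerate = FALSE)
}
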
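# L1-penalized logistic regression over the benchmark's regularization grid.
#
# The model solves
#   w_hat = argmin_w  C * l(X, y; w) + ||w||_1
# where l is the total negative log-likelihood of a logistic model and C is
# the inverse penalty strength, with an unpenalized intercept. This is
# equivalent to glmnet's binomial objective (1/n) * l + lambda * ||w||_1
# with lambda = 1 / (n * C), which is how the fit is computed.

#' Default regularization grid of C values
#'
#' 43 values evenly spaced on a log scale over \[1e-3, 1e3\] (the dense range
#' where performance varies most) concatenated with 21 values over
#' \[1e3, 1e7\] (a sparser range capturing nearly unregularized models),
#' endpoints inclusive: 64 values with 1e3 appearing twice. The duplicate is
#' retained in the grid for fidelity to the construction; reports may
#' deduplicate for display. For plotting, the conventional regularization
#' axis is alpha = 1 / C (smaller alpha = stronger regularization).
#'
#' @return Numeric vector of length 64, non-decreasing.
#' @export
default_c_grid <- function() {
  c(10^seq(-3, 3, length.out = 43), 10^seq(3, 7, length.out = 21))
}

#' Assemble the feature block for one target gene
#'
#' Appends the mutation-burden covariate `log10(count + 1)` (the +1 admits
#' zero-mutation samples) to the expression matrix as the column
#' `log10_mutation_burden`, and attaches the binary labels.
#'
#' @param expression Samples x genes numeric matrix.
#' @param mutation_counts Named non-negative per-sample burden counts.
#' @param labels Named 0/1 labels for the target gene.
#' @return A `feature_block` list with `X` (unstandardized), `y`, and
#'   `covariate` (the burden column name).
#' @export
build_features <- function(expression, mutation_counts, labels) {
  samples <- rownames(expression)
  if (is.null(samples)) stop_data("expression matrix needs sample rownames")
  if (any(mutation_counts[samples] < 0, na.rm = TRUE) ||
      anyNA(mutation_counts[samples])) {
    stop_data("mutation counts must be non-negative for every sample")
  }
  X <- cbind(expression,
             log10_mutation_burden = log10(mutation_counts[samples] + 1))
  y <- as.integer(labels[samples])
  if (anyNA(y)) stop_data("labels missing for some samples")
  structure(list(X = X, y = setNames(y, samples),
                 covariate = "log10_mutation_burden"),
            class = "feature_block")
}

#' Standardize features on training-set statistics
#'
#' Z-scores every column using the mean and sample SD of the training rows
#' only; columns with zero training variance become all-zero columns (not
#' dropped, keeping the feature space fixed). An L1 penalty is only
#' comparable across genes on a common scale, so standardization always
#' precedes the penalized fit.
#'
#' @param X Samples x features matrix.
#' @param train_ids Rownames of the training subset.
#' @return List with `X` (all rows standardized by train statistics),
#'   `center`, `scale`.
#' @export
standardize_features <- function(X, train_ids) {
  tr <- X[train_ids, , drop = FALSE]
  center <- colMeans(tr)
  scale <- apply(tr, 2L, sd)
  Xs <- sweep(X, 2L, center, "-")
  nz <- scale > 0
  Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2L, scale[nz], "/")
  Xs[, !nz] <- 0
  list(X = Xs, center = center, scale = scale)
}

single_class_error <- function(where) {
  stop(rlang::error_cnd("mutbench_single_class_error",
                        message = sprintf(
                          "training labels contain a single class (%s); skip this (gene, split)",
                          where)))
}

lambda_from_c <- function(C, n) 1 / (n * C)

#' Fit L1-penalized logistic regression at a fixed C
#'
#' Minimizes `C * l(X, y; w) + ||w||_1` (unpenalized intercept) via glmnet's
#' coordinate descent with a tight convergence threshold, warm-started along
#' a short path down to the target penalty. The predicted positive-class
#' probability for a sample is the logistic function of its linear score;
#' `P(y = 0) = 1 - P(y = 1)` exactly.
#'
#' @param X Samples x features matrix (standardize first; see
#'   [standardize_features()]).
#' @param y Binary 0/1 labels; both classes must be present.
#' @param C Inverse regularization strength, > 0.
#' @param covariate Name of the burden covariate column, excluded from the
#'   gene-feature nonzero count.
#' @return A `fitted_linear_model`: `w` (named coefficients), `intercept`,
#'   `C`, `nonzero_count` (nonzero gene coefficients), `l1_norm`, `l2_norm`.
#' @export
fit_l1_logistic <- function(X, y, C, covariate = "log10_mutation_burden") {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) single_class_error("fit_l1_logistic")
  if (min(table(y)) < 2L) {
    stop_data("each class needs at least 2 samples for the penalized fit")
  }
  if (!is.numeric(C) || C <= 0) stop_config("C must be positive")
  n <- nrow(X)
  lam <- lambda_from_c(C, n)
  path <- sort(unique(lam * c(64, 16, 4, 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1, lambda = path,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-12, maxit = 10^7)
  beta <- as.numeric(fit$beta[, length(path)])
  names(beta) <- rownames(fit$beta)
  new_fitted_linear_model(beta, fit$a0[[length(path)]], C, covariate)
}

new_fitted_linear_model <- function(w, intercept, C, covariate) {
  gene_w <- w[setdiff(names(w), covariate)]
  structure(list(
    w = w, intercept = unname(intercept), C = C,
    nonzero_count = sum(gene_w != 0),
    l1_norm = sum(abs(w)), l2_norm = sqrt(sum(w^2))
  ), class = "fitted_linear_model")
}

#' @export
predict.fitted_linear_model <- function(object, newdata, ...) {
  z <- drop(newdata[, names(object$w), drop = FALSE] %*% object$w) +
    object$intercept
  stats::plogis(z)
}

#' Sweep the regularization grid over all cross-validation splits
#'
#' For every (C, fold, seed) combination, fits on the training portion of
#' the split and scores AUPR on the train, holdout, and fixed test sets,
#' recording sparsity and coefficient norms. With the default design (4
#' folds x 2 seeds) each C value gets 8 measurements per evaluation role.
#' Features are standardized per split on the training rows. Splits whose
#' training labels collapse to a single class are skipped and recorded.
#'
#' @param block A [build_features()] block covering all samples (training
#'   context and test context).
#' @param splits A [make_splits()] assignment.
#' @param grid C values (default [default_c_grid()]).
#' @param gene,context Identifiers copied into the result rows.
#' @return A `sweep_result` tibble: `gene`, `context`, `axis` ("C"), `param`,
#'   `seed`, `fold`, `role` (train/holdout/test), `aupr`, `prevalence`,
#'   `nonzero_count`, `l1_norm`, `l2_norm`; plus a `skipped` attribute
#'   listing skipped (seed, fold) combinations and reasons.
#' @export
run_linear_sweep <- function(block, splits, grid = default_c_grid(),
                             gene = "target", context = "test") {
  design <- splits$design
  test_ids <- intersect(splits$test_ids, rownames(block$X))
  rows <- list()
  skipped <- list()
  for (s in seq_len(design$n_seeds)) {
    for (f in seq_len(design$n_folds)) {
      m <- split_members(splits, s, f)
      ytr <- block$y[m$train]
      if (length(unique(ytr)) < 2L) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          seed = s, fold = f, reason = "single-class training labels")
        next
      }
      std <- standardize_features(block$X, m$train)
      n <- length(m$train)
      lam <- lambda_from_c(grid, n)
      ulam <- sort(unique(lam), decreasing = TRUE)
      # path-level tolerance: the nearly unregularized end of the grid is
      # ill-determined under separation, but its AUPR is stable to ~1e-2
      fit <- suppressWarnings(
        glmnet::glmnet(std$X[m$train, , drop = FALSE], ytr,
                       family = "binomial", alpha = 1, lambda = ulam,
                       standardize = FALSE, intercept = TRUE,
                       thresh = 1e-7, maxit = 10^6))
      # map each grid C to its fitted column (duplicated C shares a column);
      # under separation the solver may stop early on the path, in which case
      # the smallest converged penalty stands in for the saturated tail
      col <- pmin(match(lam, ulam), length(fit$lambda))
      beta <- as.matrix(fit$beta)
      gene_rows <- setdiff(rownames(beta), block$covariate)
      nz <- colSums(beta[gene_rows, , drop = FALSE] != 0)
      l1 <- colSums(abs(beta))
      l2 <- sqrt(colSums(beta^2))
      eval_sets <- list(train = m$train, holdout = m$holdout, test = test_ids)
      scores <- lapply(eval_sets, function(ids) {
        stats::plogis(sweep(std$X[ids, rownames(beta), drop = FALSE] %*% beta,
                            2L, fit$a0, "+"))
      })
      for (role in names(eval_sets)) {
        ids <- eval_sets[[role]]
        yv <- block$y[ids]
        prev <- mean(yv)
        auprs <- if (prev > 0 && prev < 1) {
          apply(scores[[role]], 2L, aupr, labels = yv)
        } else rep(NA_real_, ncol(beta))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene = gene, context = context, axis = "C", param = grid,
          seed = s, fold = f, role = role,
          aupr = auprs[col], prevalence = prev,
          nonzero_count = nz[col], l1_norm = l1[col], l2_norm = l2[col])
      }
    }
  }
  if (length(rows) == 0L) {
    stop_data("every split was skipped; cannot sweep gene '%s'", gene)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else NULL
  class(out) <- c("sweep_result", class(out))
  out
}
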
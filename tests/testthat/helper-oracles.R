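# Independent oracles used across the suite. Each is written from the
# definition of the quantity it checks, not from the package's code path.

# Brute-force AUPR: walk every distinct score threshold (descending), count
# TP/FP/FN explicitly, and accumulate precision * recall-increment.
oracle_aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1L)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(called & labels == 1L)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Exact minimizer of the L1-penalized logistic objective
#   C * NLL(intercept, w) + ||w||_1   (intercept unpenalized)
# in the smooth split form w = w+ - w-, w+/- >= 0, via box-constrained
# L-BFGS-B with an analytic gradient.
oracle_l1_fit <- function(X, y, C) {
  p <- ncol(X)
  obj <- function(par) {
    b0 <- par[1L]; wp <- par[2:(p + 1)]; wm <- par[(p + 2):(2 * p + 1)]
    z <- drop(b0 + X %*% (wp - wm))
    C * sum(log1p(exp(z)) - y * z) + sum(wp) + sum(wm)
  }
  grad <- function(par) {
    b0 <- par[1L]; wp <- par[2:(p + 1)]; wm <- par[(p + 2):(2 * p + 1)]
    z <- drop(b0 + X %*% (wp - wm))
    r <- stats::plogis(z) - y
    g <- drop(crossprod(X, r))
    c(C * sum(r), C * g + 1, -C * g + 1)
  }
  o <- stats::optim(rep(0, 2 * p + 1), obj, grad, method = "L-BFGS-B",
                    lower = c(-Inf, rep(0, 2 * p)),
                    control = list(maxit = 20000, factr = 10))
  list(intercept = o$par[1L],
       w = o$par[2:(p + 1)] - o$par[(p + 2):(2 * p + 1)])
}

# Naive enumeration of the two selection rules. "Stronger regularization"
# follows the axis orientation passed as +1 (larger value = stronger) or -1.
oracle_select <- function(params, means, ses, orientation) {
  best_mean <- max(means)
  best_cands <- params[means == best_mean]
  best <- if (orientation < 0) min(best_cands) else max(best_cands)
  se_best <- ses[match(best, params)]
  qualifying <- params[means >= best_mean - se_best]
  smallest_good <- if (orientation < 0) min(qualifying) else max(qualifying)
  list(best = best, smallest_good = smallest_good)
}

# Small strong-signal two-context cohort used by several suites.
tiny_cohort <- function(seed = 1, effect = 2, shift = 0, n_per = 120,
                        n_targets = 2, n_genes = 30, prevalence = 0.3) {
  generate_cohort(cohort_config(
    n_contexts = 2, n_samples_per_context = n_per, n_genes = n_genes,
    n_target_genes = n_targets, n_informative = 3, effect_size = effect,
    context_shift = shift, prevalence_per_context = prevalence, seed = seed))
}

# Labels + feature block + splits for one target gene of a cohort.
gene_setup <- function(cohort, gene = "TG01", n_seeds = 2) {
  role <- cohort$gene_roles$role[match(gene, cohort$gene_roles$gene)]
  calls <- threshold_cnv(cohort$cnv_values)
  labels <- label_samples(cohort$point_mutations[, gene], calls[, gene],
                          role, gene = gene)
  design <- experiment_design("cross_dataset", "context_1", "context_2",
                              n_seeds = n_seeds)
  splits <- suppressWarnings(make_splits(cohort$annotations, labels, design))
  block <- build_features(
    cohort$expression,
    setNames(cohort$annotations$mutation_count, cohort$annotations$sample_id),
    labels)
  list(labels = labels, design = design, splits = splits, block = block)
}
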
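# Synthetic multi-context cohort generator.
#
# Emulates the statistical structure the benchmark assumes: several
# datasets/contexts with per-context mutation prevalence, expression features
# causally shifted by mutation status, context-specific covariate shift that
# controls the generalization gap, long-tailed mutation-burden counts with
# hypermutated outliers, and copy-number values on a log scale centered at
# the diploid value 1.0.

#' Configuration for the synthetic cohort generator
#'
#' @param n_contexts Number of datasets/contexts (>= 1).
#' @param n_samples_per_context Samples per context.
#' @param n_genes Number of expression features.
#' @param n_target_genes Number of target genes to label (each gets its own
#'   disjoint block of informative expression features).
#' @param n_informative Number of expression features per target gene whose
#'   mean depends on that gene's mutation status. Requires
#'   `n_target_genes * n_informative <= n_genes`.
#' @param effect_size Mean expression shift, in SD units, between mutated and
#'   non-mutated samples for informative features.
#' @param context_shift Mean expression shift added to informative features
#'   in the designated shifted contexts (covariate shift; drives the
#'   generalization gap).
#' @param informative_correlation Pairwise noise correlation within a target
#'   gene's informative block (co-expression module structure, in `[0, 1)`).
#'   Correlated informative features are near-interchangeable proxies for
#'   the underlying signal, which flattens the regularization/performance
#'   curve the way redundant transcriptomic signatures do.
#' @param prevalence_per_context Mutation probability per context, each in
#'   (0, 1); recycled across contexts.
#' @param hypermutation_rate Fraction of samples drawn from the outlier
#'   burden distribution (burden scaled x50).
#' @param cnv_event_rate Probability that a positive sample's label is driven
#'   by a copy-number event rather than a point mutation.
#' @param n_cancer_types Cancer types per context, assigned round-robin.
#' @param shifted_contexts Integer indices of contexts receiving the
#'   covariate shift; defaults to the last context (the conventional held-out
#'   context).
#' @param seed Integer seed; equal configurations yield identical cohorts.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_contexts = 2L,
                          n_samples_per_context = 200L,
                          n_genes = 120L,
                          n_target_genes = 20L,
                          n_informative = 5L,
                          effect_size = 0.8,
                          context_shift = 0,
                          informative_correlation = 0.7,
                          prevalence_per_context = 0.3,
                          hypermutation_rate = 0.02,
                          cnv_event_rate = 0.25,
                          n_cancer_types = 3L,
                          shifted_contexts = NULL,
                          seed = 1L) {
  cfg <- list(
    n_contexts = n_contexts,
    n_samples_per_context = n_samples_per_context,
    n_genes = n_genes,
    n_target_genes = n_target_genes,
    n_informative = n_informative,
    effect_size = effect_size,
    context_shift = context_shift,
    informative_correlation = informative_correlation,
    prevalence_per_context = rep_len(prevalence_per_context, n_contexts),
    hypermutation_rate = hypermutation_rate,
    cnv_event_rate = cnv_event_rate,
    n_cancer_types = n_cancer_types,
    shifted_contexts = shifted_contexts %||%
      (if (n_contexts > 1L) n_contexts else integer(0)),
    seed = seed
  )
  for (f in c("n_contexts", "n_samples_per_context", "n_genes",
              "n_target_genes", "n_informative", "n_cancer_types")) {
    if (!is_count(cfg[[f]])) stop_config("invalid config field '%s': must be a positive count", f)
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (cfg$n_target_genes * cfg$n_informative > cfg$n_genes) {
    stop_config("invalid config field 'n_informative': n_target_genes * n_informative exceeds n_genes")
  }
  if (any(cfg$prevalence_per_context <= 0 | cfg$prevalence_per_context >= 1)) {
    stop_config("invalid config field 'prevalence_per_context': values must lie in (0, 1)")
  }
  if (!is.numeric(cfg$informative_correlation) ||
      cfg$informative_correlation < 0 || cfg$informative_correlation >= 1) {
    stop_config("invalid config field 'informative_correlation': must lie in [0, 1)")
  }
  for (f in c("effect_size", "context_shift")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]])) {
      stop_config("invalid config field '%s': must be a finite number", f)
    }
  }
  if (cfg$hypermutation_rate < 0 || cfg$hypermutation_rate >= 0.5) {
    stop_config("invalid config field 'hypermutation_rate': must lie in [0, 0.5)")
  }
  if (cfg$cnv_event_rate < 0 || cfg$cnv_event_rate > 1) {
    stop_config("invalid config field 'cnv_event_rate': must lie in [0, 1]")
  }
  if (length(cfg$shifted_contexts) > 0 &&
      (any(cfg$shifted_contexts < 1) || any(cfg$shifted_contexts > cfg$n_contexts))) {
    stop_config("invalid config field 'shifted_contexts': indices outside 1..n_contexts")
  }
  if (!is_count(abs(cfg$seed) + 1)) stop_config("invalid config field 'seed': must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "cohort_config")
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated normal draw via inverse-CDF, used so neutral/gain/loss CNV draws
# never cross the call thresholds (keeps truth labels exactly recoverable).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic multi-context cohort
#'
#' Informative expression features for target gene t follow
#' `Normal(effect_size * m_t * label_t + shift_offset, 1)`; background
#' features are standard normal. The per-gene multipliers `m_t` spread
#' evenly over \[0.5, 1.5\] (mean 1), mimicking how driver genes differ in
#' the strength of their transcriptional footprint. In shifted contexts,
#' `shift_offset` has mean `context_shift` with per-cancer-type
#' heterogeneity of the same magnitude (see the source note in this file). Mutation-burden counts are log-normal with a
#' x50-scaled hypermutated subpopulation. Copy-number values sit at
#' `Normal(1, 0.1)` (diploid center) for neutral samples, with label-driving
#' events placed beyond the gain/loss thresholds `log2(5/2)` / `log2(3/2)`
#' in the role-concordant direction. A positive sample's label is driven by a
#' copy-number event with probability `cnv_event_rate`, otherwise by a point
#' mutation.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list with elements `expression` (samples x
#'   genes matrix), `annotations` (tibble: sample_id, context, cancer_type,
#'   mutation_count), `point_mutations` (samples x target genes 0/1 matrix),
#'   `cnv_values` (samples x target genes continuous matrix), `gene_roles`
#'   (tibble: gene, role), and `truth` (labels matrix, informative-feature
#'   map, hypermutated flags, shifted contexts, config).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_contexts * cfg$n_samples_per_context
  sample_id <- sprintf("S%05d", seq_len(n))
  context <- rep(sprintf("context_%d", seq_len(cfg$n_contexts)),
                 each = cfg$n_samples_per_context)
  cancer_type <- paste0("type_", LETTERS[
    rep_len(seq_len(cfg$n_cancer_types), cfg$n_samples_per_context)])
  cancer_type <- rep(cancer_type[seq_len(cfg$n_samples_per_context)],
                     times = cfg$n_contexts)

  # mutation burden: log-normal background, x50 hypermutated outliers
  burden <- pmax(1, round(rlnorm(n, meanlog = log(30), sdlog = 0.6)))
  hyper <- runif(n) < cfg$hypermutation_rate
  burden[hyper] <- burden[hyper] * 50

  target_genes <- sprintf("TG%02d", seq_len(cfg$n_target_genes))
  roles <- rep_len(c("oncogene", "tumor_suppressor"), cfg$n_target_genes)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  prev <- cfg$prevalence_per_context[match(
    context, sprintf("context_%d", seq_len(cfg$n_contexts)))]
  labels <- matrix(0L, n, cfg$n_target_genes,
                   dimnames = list(sample_id, target_genes))
  point <- labels
  cnv <- matrix(rtruncnorm(n * cfg$n_target_genes, 1, 0.1,
                           lower = log2(3 / 2) + 0.01,
                           upper = log2(5 / 2) - 0.01),
                n, cfg$n_target_genes,
                dimnames = list(sample_id, target_genes))
  for (t in seq_len(cfg$n_target_genes)) {
    y <- rbinom(n, 1L, prev)
    labels[, t] <- y
    pos <- which(y == 1L)
    via_cnv <- pos[runif(length(pos)) < cfg$cnv_event_rate]
    via_point <- setdiff(pos, via_cnv)
    point[via_point, t] <- 1L
    if (length(via_cnv) > 0) {
      if (roles[t] == "oncogene") {
        cnv[via_cnv, t] <- rtruncnorm(length(via_cnv), 1.6, 0.1,
                                      lower = log2(5 / 2) + 0.01)
      } else {
        cnv[via_cnv, t] <- rtruncnorm(length(via_cnv), 0.3, 0.1,
                                      lower = 0, upper = log2(3 / 2) - 0.01)
      }
    }
  }

  shifted <- context %in% sprintf("context_%d", cfg$shifted_contexts)
  # Covariate shift: informative features in a shifted context are offset by
  # context_shift on average, but the offset is heterogeneous across the
  # context's cancer types (unit-SD centered weights, so the per-sample
  # offsets have mean and SD both equal to context_shift). A perfectly
  # uniform offset would shift every linear score by the same constant and
  # leave rank-based metrics such as AUPR untouched; the between-type spread
  # is what scrambles the pooled ranking and degrades generalization.
  type_levels <- sort(unique(cancer_type))
  type_w <- if (length(type_levels) > 1L) {
    w <- seq_along(type_levels) - mean(seq_along(type_levels))
    w / sd(w)
  } else 0
  shift_offset <- cfg$context_shift * shifted *
    (1 + type_w[match(cancer_type, type_levels)])
  expr <- matrix(rnorm(n * cfg$n_genes), n, cfg$n_genes,
                 dimnames = list(sample_id, genes))
  # Per-gene effect heterogeneity: target genes differ in how strongly
  # mutation status perturbs expression (as driver genes do), with
  # multipliers evenly spread over [0.5, 1.5] x effect_size (mean 1).
  effect_mult <- if (cfg$n_target_genes > 1L) {
    seq(0.5, 1.5, length.out = cfg$n_target_genes)
  } else 1
  informative <- list()
  rho <- cfg$informative_correlation
  for (t in seq_len(cfg$n_target_genes)) {
    block <- genes[((t - 1L) * cfg$n_informative + 1L):(t * cfg$n_informative)]
    informative[[target_genes[t]]] <- block
    # shared module noise: features in a block are correlated proxies (unit
    # variance, pairwise correlation rho) for the same signal
    module <- rnorm(n)
    expr[, block] <- sqrt(1 - rho) * expr[, block] +
      sqrt(rho) * module +
      cfg$effect_size * effect_mult[t] * labels[, t] + shift_offset
  }

  structure(list(
    expression = expr,
    annotations = tibble::tibble(
      sample_id = sample_id, context = context,
      cancer_type = cancer_type, mutation_count = as.integer(burden)),
    point_mutations = point,
    cnv_values = cnv,
    gene_roles = tibble::tibble(gene = target_genes, role = roles),
    truth = list(labels = labels, informative = informative,
                 effect_multipliers = setNames(effect_mult, target_genes),
                 hypermutated = setNames(hyper, sample_id),
                 shifted_contexts = cfg$shifted_contexts,
                 config = cfg)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0(
    "synthetic_cohort: %d samples x %d expression features, ",
    "%d target genes, %d context(s)\n"),
    nrow(x$expression), ncol(x$expression),
    ncol(x$point_mutations), cfg$n_contexts))
  cat(sprintf("  effect_size = %g SD, context_shift = %g SD (contexts: %s)\n",
              cfg$effect_size, cfg$context_shift,
              if (length(cfg$shifted_contexts)) {
                paste(cfg$shifted_contexts, collapse = ", ")
              } else "none"))
  invisible(x)
}

#' Inject additional hypermutated samples into a cohort
#'
#' Marks a fraction of non-hypermutated samples as hypermutated by scaling
#' their burden counts far above the background (x50 the background maximum),
#' and records them in the truth slot. With `fraction = 0` the cohort is
#' returned unchanged. Note that for fractions above roughly 0.2 the
#' mean + 2 SD rule cannot flag every injected sample (at most a quarter of
#' any distribution lies two SDs above its mean, by Chebyshev's inequality),
#' so the guarantee that injected samples exceed that threshold holds for
#' small fractions only.
#'
#' @param cohort A `synthetic_cohort`.
#' @param fraction Fraction of samples to inject, in `[0, 0.5)`.
#' @param seed Seed for choosing which samples are injected; defaults to the
#'   cohort's seed + 1.
#' @return The modified cohort, with `truth$injected_hypermutated` naming the
#'   injected samples.
#' @export
inject_hypermutated <- function(cohort, fraction,
                                seed = cohort$truth$config$seed + 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 0.5) {
    stop_config("fraction must lie in [0, 0.5)")
  }
  if (fraction == 0) return(cohort)
  ann <- cohort$annotations
  eligible <- ann$sample_id[!cohort$truth$hypermutated]
  k <- round(fraction * nrow(ann))
  chosen <- with_seed(seed, sample(eligible, min(k, length(eligible))))
  background_max <- max(ann$mutation_count[!ann$sample_id %in% chosen])
  idx <- match(chosen, ann$sample_id)
  ann$mutation_count[idx] <- as.integer(50L * background_max)
  cohort$annotations <- ann
  cohort$truth$hypermutated[idx] <- TRUE
  cohort$truth$injected_hypermutated <- chosen
  cohort
}
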
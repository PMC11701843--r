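test_that("cancer-type validity needs >= 15 mutated and >= 5% mutated", {
  types <- rep(c("A", "B", "C"), c(100, 100, 400))
  labels <- c(rep(1, 20), rep(0, 80),    # A: 20/100 -> valid
              rep(1, 14), rep(0, 86),    # B: 14/100 -> fails count
              rep(1, 15), rep(0, 385))   # C: 15/400 = 3.75% -> fails proportion
  expect_equal(valid_cancer_types(labels, types), "A")
  expect_error(valid_cancer_types(integer(0), character(0)),
               class = "mutbench_data_error")
})

test_that("validity rule matches brute-force counting on random tables", {
  set.seed(8)
  for (i in 1:30) {
    n <- 600
    types <- sample(LETTERS[1:5], n, replace = TRUE)
    labels <- rbinom(n, 1, runif(1, 0.02, 0.4))
    got <- valid_cancer_types(labels, types)
    want <- character(0)
    for (ty in sort(unique(types))) {
      idx <- types == ty
      if (sum(labels[idx]) >= 15 && mean(labels[idx]) >= 0.05) {
        want <- c(want, ty)
      }
    }
    expect_equal(got, want)
  }
})

test_that("gene retention follows the per-mode rules", {
  sets <- list(
    tcga = list(g1 = c("A"), g2 = c("A", "B"), g3 = character(0)),
    ccle = list(g1 = c("B"), g2 = character(0), g3 = c("A"))
  )
  # cross-dataset: >= 1 valid type in each dataset
  expect_equal(retain_genes(sets, "cross_dataset"), "g1")
  # single dataset: >= 2 valid types
  expect_equal(retain_genes(sets$tcga, "cancer_type_holdout"), "g2")
  # no valid types anywhere -> dropped in both modes
  expect_false("g3" %in% retain_genes(sets, "cross_dataset"))
  expect_false("g3" %in% retain_genes(sets$tcga, "cancer_type_holdout"))
})

test_that("modality intersection restricts samples and genes deterministically", {
  e <- matrix(rnorm(9), 3, 3,
              dimnames = list(c("s3", "s1", "s2"), c("gB", "gA", "gC")))
  ann <- tibble::tibble(sample_id = c("s2", "s3", "s4"),
                        cancer_type = "A", context = "d1")
  labels <- setNames(c(1, 0, 1), c("s2", "s3", "s4"))
  out <- intersect_modalities(e, ann, labels = labels)
  expect_equal(rownames(out$expression), c("s2", "s3")) # sorted intersection
  expect_equal(colnames(out$expression), c("gA", "gB", "gC"))
  expect_equal(names(out$labels), c("s2", "s3"))

  # gene intersection across datasets
  e2 <- matrix(rnorm(4), 2, 2, dimnames = list(c("s2", "s3"), c("gA", "gB")))
  out2 <- intersect_modalities(list(d1 = e, d2 = e2), ann)
  expect_equal(colnames(out2$expression$d1), c("gA", "gB"))
  expect_equal(colnames(out2$expression$d2), c("gA", "gB"))

  bad <- matrix(0, 1, 1, dimnames = list("zz", "gA"))
  expect_error(intersect_modalities(bad, ann), class = "mutbench_data_error")
})

test_that("splits keep the held-out context fixed and partition the rest", {
  co <- tiny_cohort(seed = 2, n_per = 160)
  gs <- gene_setup(co)
  sp <- gs$splits
  test_ids <- co$annotations$sample_id[co$annotations$context == "context_2"]
  expect_setequal(sp$test_ids, test_ids)
  non_test <- setdiff(co$annotations$sample_id, test_ids)
  for (s in 1:2) {
    fl <- sp$folds[sp$folds$seed == s, ]
    # exhaustive and disjoint: every non-test sample in exactly one fold
    expect_setequal(fl$sample_id, non_test)
    expect_false(anyDuplicated(fl$sample_id) > 0)
    for (f in 1:4) {
      m <- split_members(sp, s, f)
      expect_length(intersect(m$train, m$holdout), 0)
      expect_length(intersect(c(m$train, m$holdout), test_ids), 0) # no leakage
      expect_setequal(c(m$train, m$holdout), non_test)
    }
  }
  # determinism: rebuilding with the same design gives identical folds
  sp2 <- suppressWarnings(make_splits(co$annotations, gs$labels, gs$design))
  expect_identical(sp$folds, sp2$folds)
})

test_that("stratified folds keep label prevalence within 0.05 for large strata", {
  co <- generate_cohort(cohort_config(
    n_contexts = 2, n_samples_per_context = 600, n_genes = 10,
    n_target_genes = 1, n_informative = 1, n_cancer_types = 2,
    prevalence_per_context = 0.2, seed = 31))
  gs <- gene_setup(co)
  pool <- gs$splits$folds[gs$splits$folds$seed == 1, ]
  overall <- mean(gs$labels[pool$sample_id])
  for (f in 1:4) {
    ids <- pool$sample_id[pool$fold == f]
    expect_lt(abs(mean(gs$labels[ids]) - overall), 0.05)
  }
})

test_that("small strata trigger the label-only downgrade warning", {
  ann <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:43),
    context = c(rep("d1", 40), rep("d2", 3)),
    cancer_type = c(rep("A", 37), rep("rare", 3), rep("B", 3)))
  labels <- setNames(c(rbinom(37, 1, 0.5), 1, 1, 1, 0, 1, 0), ann$sample_id)
  design <- experiment_design("cross_dataset", "d1", "d2")
  expect_warning(make_splits(ann, labels, design), "label-only")
})

test_that("experiment design enforces the fold/holdout arithmetic", {
  d <- experiment_design("cross_dataset", "a", "b")
  expect_equal(d$n_folds, 4L)
  expect_equal(d$n_seeds, 2L)
  expect_equal(d$train_fraction, 0.75)
  expect_error(experiment_design("cross_dataset", "a", "b", train_fraction = 0.8),
               class = "mutbench_config_error")
})
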
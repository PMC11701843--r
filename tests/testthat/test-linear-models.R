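test_that("the default C grid concatenates the dense and sparse log ranges", {
  g <- default_c_grid()
  expect_length(g, 64)
  expect_equal(g[1], 1e-3)
  expect_equal(g[64], 1e7)
  expect_equal(sum(g == 1e3), 2) # shared endpoint appears twice
  expect_true(all(diff(g) >= 0))
  expect_true(all(g > 0))
  # dense part: 43 log-even values over [1e-3, 1e3]
  expect_equal(g[1:43], 10^seq(-3, 3, length.out = 43))
})

test_that("feature blocks append the smoothed burden covariate and standardize cleanly", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
  X[, 3] <- 5 # constant gene
  counts <- setNames(c(1000, rep(10, 9)), rownames(X))
  y <- setNames(rep(c(0, 1), 5), rownames(X))
  blk <- build_features(X, counts, y)
  expect_equal(unname(blk$X["s1", "log10_mutation_burden"]), log10(1001))
  expect_lt(abs(blk$X["s1", "log10_mutation_burden"] - 3), 1e-3)

  std <- standardize_features(blk$X, rownames(X)[1:8])
  expect_true(all(abs(colMeans(std$X[1:8, std$scale > 0])) < 1e-9))
  expect_true(all(std$X[, "g3"] == 0)) # zero-variance column, kept as zeros
  expect_error(build_features(X, counts - 20, y), class = "mutbench_data_error")
})

test_that("extreme regularization reduces to the intercept-only mean predictor", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4,
              dimnames = list(paste0("s", 1:50), paste0("g", 1:4)))
  y <- rbinom(50, 1, 0.3)
  y[1:2] <- c(0, 1)
  f <- fit_l1_logistic(X, y, C = 1e-6, covariate = "none")
  expect_equal(f$nonzero_count, 0)
  expect_true(all(f$w == 0))
  p <- predict(f, X)
  expect_lt(max(abs(p - mean(y))), 0.01)
  # complement rule to machine precision
  expect_equal(1 - p, stats::plogis(-(f$intercept)) + p * 0, tolerance = 1e-12)
})

test_that("fitted coefficients match the brute-force objective minimizer on toys", {
  set.seed(4)
  tried <- 0
  while (tried < 10) {
    n <- sample(4:6, 1)
    p <- sample(2:3, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rbinom(n, 1, 0.5)
    if (min(table(factor(y, c(0, 1)))) < 2) next
    tried <- tried + 1
    for (C in c(0.5, 10)) {
      f <- suppressWarnings(fit_l1_logistic(X, y, C, covariate = "none"))
      o <- oracle_l1_fit(X, y, C)
      expect_lt(max(abs(c(f$w - o$w, f$intercept - o$intercept))), 1e-4)
    }
  }
  expect_error(fit_l1_logistic(matrix(0, 4, 2), rep(1, 4), 1),
               class = "mutbench_single_class_error")
})

test_that("regularization path is monotone in norms and sparsity", {
  co <- tiny_cohort(seed = 6)
  gs <- gene_setup(co)
  sw <- run_linear_sweep(gs$block, gs$splits, gene = "TG01",
                         context = "context_2")
  one <- sw[sw$role == "train" & sw$seed == 1 & sw$fold == 1, ]
  one <- one[order(one$param), ]
  # l1 norm non-decreasing in C (up to solver noise)
  expect_true(all(diff(one$l1_norm) > -0.05))
  # sparsity strongly rank-correlated with C
  expect_gt(cor(one$param, one$nonzero_count, method = "spearman"), 0.9)
})

test_that("the sweep records 8 measurements per C and the overfitting direction", {
  co <- tiny_cohort(seed = 10)
  gs <- gene_setup(co)
  sw <- run_linear_sweep(gs$block, gs$splits, gene = "TG01",
                         context = "context_2")
  # 64 C values x 4 folds x 2 seeds x 3 roles
  expect_equal(nrow(sw), 64 * 8 * 3)
  counts <- table(sw$param[sw$role == "holdout"])
  # 8 measurements per distinct C; the duplicated 1e3 grid entry doubles up
  expect_true(all(counts[names(counts) != "1000"] == 8))
  expect_equal(unname(counts["1000"]), 16)
  # train AUPR at the least-regularized C dominates holdout
  biggest <- max(sw$param)
  tr <- mean(sw$aupr[sw$role == "train" & sw$param == biggest])
  ho <- mean(sw$aupr[sw$role == "holdout" & sw$param == biggest])
  expect_gte(tr, ho)
})

test_that("the best-holdout C mostly selects truth-informative features", {
  co <- tiny_cohort(seed = 12, effect = 2)
  gs <- gene_setup(co)
  sw <- run_linear_sweep(gs$block, gs$splits, gene = "TG01",
                         context = "context_2")
  best <- select_best(summarize_parameters(sw))
  m <- split_members(gs$splits, 1, 1)
  std <- standardize_features(gs$block$X, m$train)
  f <- fit_l1_logistic(std$X[m$train, ], gs$block$y[m$train], best)
  hits <- names(f$w)[f$w != 0 & names(f$w) != "log10_mutation_burden"]
  informative <- co$truth$informative[["TG01"]]
  expect_gt(mean(hits %in% informative), 0.5)
})

test_that("single-class training splits are skipped and recorded", {
  co <- tiny_cohort(seed = 14, n_per = 80, prevalence = 0.3)
  gs <- gene_setup(co)
  # degenerate labels: all negative in the training context
  labs <- gs$labels
  labs[] <- 0L
  labs[gs$splits$test_ids] <- rep_len(c(0L, 1L), length(gs$splits$test_ids))
  blk <- gs$block
  blk$y <- labs
  expect_error(run_linear_sweep(blk, gs$splits), class = "mutbench_data_error")
})
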
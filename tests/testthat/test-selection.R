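make_summary <- function(params, means, ses, m = 8L, axis = "C") {
  out <- tibble::tibble(param = params, mean_aupr = means, se = ses, m = m)
  attr(out, "axis") <- axis
  class(out) <- c("parameter_summary", class(out))
  out
}

test_that("best selection takes the argmax with ties toward stronger regularization", {
  s <- make_summary(c(0.01, 1, 100), c(0.5, 0.6, 0.55), c(0.02, 0.02, 0.02))
  expect_equal(select_best(s), 1)
  tie <- make_summary(c(0.01, 100), c(0.6, 0.6), c(0.02, 0.02))
  expect_equal(select_best(tie), 0.01) # smaller C = stronger
  # orientation flips for dropout
  tie_d <- make_summary(c(0.1, 0.9), c(0.6, 0.6), c(0.02, 0.02), axis = "dropout")
  expect_equal(select_best(tie_d), 0.9)
  single <- make_summary(3, 0.4, 0.01)
  expect_equal(select_best(single), 3)
  expect_error(select_best(make_summary(numeric(0), numeric(0), numeric(0))),
               class = "mutbench_data_error")
})

test_that("smallest-good selection applies the one-standard-error rule", {
  # means {strong 0.57, mid 0.58, weak(best) 0.60}, SE(best) 0.05 ->
  # threshold 0.55, all qualify, strongest (smallest C) wins
  s <- make_summary(c(0.01, 1, 100), c(0.57, 0.58, 0.60), c(0.01, 0.01, 0.05))
  expect_equal(select_smallest_good(s), 0.01)
  # strong model far below: best is its own smallest good
  s2 <- make_summary(c(0.01, 100), c(0.40, 0.60), c(0.01, 0.05))
  expect_equal(select_smallest_good(s2), 100)
  # SE = 0 boundary: only exact matches of the best mean qualify
  s3 <- make_summary(c(0.01, 1, 100), c(0.599, 0.60, 0.60), c(0, 0, 0))
  expect_equal(select_smallest_good(s3), 1)
  # m < 2 makes the SE undefined
  s4 <- make_summary(c(0.01, 1), c(0.5, 0.6), c(NA, NA), m = 1L)
  expect_error(select_smallest_good(s4), class = "mutbench_data_error")
})

test_that("selection rules agree with naive enumeration on random summaries", {
  set.seed(30)
  for (axis in c("C", "hidden_size", "dropout", "weight_decay")) {
    orient <- axis_orientation(axis)
    for (i in 1:50) {
      k <- sample(3:10, 1)
      s <- make_summary(sort(sample(1:100, k)),
                        round(runif(k, 0.2, 0.8), 2),
                        round(runif(k, 0, 0.1), 3), axis = axis)
      want <- oracle_select(s$param, s$mean_aupr, s$se, orient)
      expect_equal(select_best(s), want$best)
      expect_equal(select_smallest_good(s), want$smallest_good)
      # invariants: never below the 1-SE threshold; never less regularized
      got <- select_smallest_good(s)
      i_best <- match(want$best, s$param)
      expect_gte(s$mean_aupr[match(got, s$param)],
                 s$mean_aupr[i_best] - s$se[i_best])
      expect_gte(orient * (got - want$best), 0)
    }
  }
})

sweep_fixture <- function(holdout_by_param, test_by_param, m = 4L) {
  # builds a minimal sweep with per-(param, fold) jitter-free measurements
  params <- as.numeric(names(holdout_by_param))
  rows <- list()
  for (i in seq_along(params)) {
    for (f in seq_len(m)) {
      jit <- (f - mean(seq_len(m))) / 100 # symmetric, mean-preserving
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = "G", context = "ctx", axis = "C", param = params[i],
        seed = 1L, fold = f,
        role = c("holdout", "test"),
        aupr = c(holdout_by_param[[i]] + jit, test_by_param[[i]] + jit),
        prevalence = 0.3, nonzero_count = NA_integer_,
        l1_norm = NA_real_, l2_norm = NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

test_that("strategy comparison reports exact zero when one model wins both criteria", {
  sw <- sweep_fixture(c(`0.1` = 0.3, `10` = 0.6), c(`0.1` = 0.2, `10` = 0.5))
  rep <- compare_strategies(sw)
  expect_equal(rep$best_param, 10)
  expect_equal(rep$smallest_good_param, 10)
  expect_identical(rep$difference, 0)
})

test_that("a qualifying-but-worse small model yields a positive difference", {
  # the strong model is within 1 SE on holdout but generalizes worse
  sw <- sweep_fixture(c(`0.1` = 0.595, `10` = 0.6),
                      c(`0.1` = 0.30, `10` = 0.55))
  rep <- compare_strategies(sw)
  expect_equal(rep$best_param, 10)
  expect_equal(rep$smallest_good_param, 0.1)
  expect_gt(rep$difference, 0.2)
})

test_that("selection never reads test measurements before choosing", {
  sw <- sweep_fixture(c(`0.1` = 0.4, `1` = 0.55, `10` = 0.6),
                      c(`0.1` = 0.3, `1` = 0.5, `10` = 0.55))
  rep1 <- compare_strategies(sw)
  # corrupt the test rows wildly: chosen parameters must not move
  sw2 <- sw
  sw2$aupr[sw2$role == "test"] <- rev(sw2$aupr[sw2$role == "test"])
  rep2 <- compare_strategies(sw2)
  expect_equal(rep2$best_param, rep1$best_param)
  expect_equal(rep2$smallest_good_param, rep1$smallest_good_param)
})

test_that("the Wilcoxon comparison behaves at its edges and under the null", {
  # antisymmetric vector: statistic at the null center
  d <- c(0.1, -0.1, 0.2, -0.2, 0.05, -0.05)
  res <- strategy_wilcoxon(d)
  expect_gt(res$p_value, 0.9)
  # all positive: decisive
  res2 <- strategy_wilcoxon(rep(c(0.05, 0.1), 10))
  expect_lt(res2$p_value, 0.01)
  # all zero: degenerate, p = 1
  res3 <- strategy_wilcoxon(rep(0, 5))
  expect_true(res3$degenerate)
  expect_equal(res3$p_value, 1)
  # under a continuous null, p-values behave like a valid test's: roughly
  # uniform (checked on coarse summaries; the exact signed-rank null is
  # discrete, so a literal distribution test would be miscalibrated)
  set.seed(31)
  ps <- replicate(200, strategy_wilcoxon(rnorm(15))$p_value)
  expect_lt(mean(ps <= 0.05), 0.10)
  expect_gt(mean(ps <= 0.5), 0.35)
  expect_lt(abs(mean(ps) - 0.5), 0.08)
})
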
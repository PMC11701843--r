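test_that("AUPR matches exhaustive PR enumeration on all small configurations", {
  # every binary labeling of two fixed score vectors (with and without ties),
  # n up to 6, skipping single-class labelings
  score_sets <- list(
    c(0.9, 0.7, 0.5, 0.4, 0.2, 0.1),          # distinct
    c(0.9, 0.7, 0.7, 0.4, 0.4, 0.4)           # tied groups
  )
  for (scores in score_sets) {
    for (n in 2:6) {
      s <- scores[seq_len(n)]
      for (mask in 1:(2^n - 2)) {
        y <- as.integer(intToBits(mask)[seq_len(n)])
        expect_equal(aupr(s, y), oracle_aupr(s, y), tolerance = 1e-12)
      }
    }
  }
})

test_that("AUPR handles canonical cases and errors", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # scores reversed on labels (1, 0): positive ranked last
  expect_equal(aupr(c(0.2, 0.9), c(1, 0)), 0.5)
  # monotone-transform invariance
  s <- c(0.1, 0.5, 0.3, 0.9, 0.2)
  y <- c(0, 1, 0, 1, 1)
  expect_equal(aupr(s, y), aupr(exp(3 * s), y))
  expect_error(aupr(c(1, 2), c(1, 1)), class = "mutbench_data_error")
})

test_that("random-score AUPR averages to the prevalence", {
  # note: the average-precision estimator slightly exceeds the prevalence at
  # finite n, so the sample must be large enough for the bias to sit inside
  # the tolerance
  set.seed(42)
  y <- rep(c(1, 0), c(150, 350))
  vals <- replicate(1000, aupr(runif(500), y))
  expect_lt(abs(mean(vals) - 0.3), 0.02)
})

test_that("constant-score classifier has corrected AUPR exactly 0", {
  set.seed(7)
  for (i in 1:20) {
    y <- rbinom(500, 1, runif(1, 0.1, 0.9))
    if (length(unique(y)) < 2) next
    raw <- aupr(rep(0.5, 500), y)
    expect_equal(corrected_aupr(raw, mean(y)), 0, tolerance = 1e-12)
  }
})

test_that("baseline correction and generalization difference follow the sign convention", {
  expect_equal(corrected_aupr(1.0, 0.2), 0.8)
  expect_equal(corrected_aupr(0.25, 0.25), 0)
  expect_equal(corrected_aupr(0.75, 0.25), 0.5)
  expect_error(corrected_aupr(0.5, 0), class = "mutbench_data_error")
  expect_error(corrected_aupr(0.5, 1), class = "mutbench_data_error")
  # positive difference = poor generalization (holdout better than test)
  expect_equal(generalization_difference(0.5, 0.1, 0.2, 0.1), 0.3)
  expect_equal(generalization_difference(0.2, 0.1, 0.5, 0.1), -0.3)
  expect_equal(generalization_difference(0.4, 0.2, 0.4, 0.2), 0)
})

test_that("bootstrap CI is a percentile interval around the estimate", {
  set.seed(11)
  y <- rep(c(1, 0), each = 100)
  s <- c(rnorm(100, 3), rnorm(100, 0)) # strong separation
  ci <- bootstrap_ci(s, y, B = 1000)
  expect_lt(ci["upper"] - ci["lower"], 0.05)
  expect_gte(1.0, ci["lower"])
  expect_true(ci["estimate"] >= ci["lower"] - 1e-12 &&
                ci["estimate"] <= ci["upper"] + 1e-12)
})

test_that("bootstrap CI coverage for AUPR is near nominal", {
  # moderate-signal population; truth taken as AUPR on a large sample
  set.seed(99)
  gen <- function(n) {
    y <- rbinom(n, 1, 0.3)
    list(y = y, s = rnorm(n, mean = 1.2 * y))
  }
  big <- gen(40000)
  truth <- aupr(big$s, big$y)
  hits <- 0
  reps <- 120
  for (i in seq_len(reps)) {
    d <- gen(200)
    ci <- bootstrap_ci(d$s, d$y, B = 300)
    if (truth >= ci["lower"] && truth <= ci["upper"]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.85)
  expect_lte(hits / reps, 1.0)
})

test_that("rank analysis ranks axis values per gene and counts around the median", {
  k <- 10
  params <- seq_len(k) * 10
  # gene A: strictly increasing performance in the axis value
  a <- tibble::tibble(gene = "A", param = params,
                      aupr = seq(0.1, 0.9, length.out = k))
  # gene B: all tied
  b <- tibble::tibble(gene = "B", param = params, aupr = 0.5)
  rt <- rank_axis(dplyr::bind_rows(a, b))
  expect_equal(rt$median_rank, 5.5)
  expect_equal(rt$ranks$rank[rt$ranks$gene == "A" & rt$ranks$param == max(params)], 1)
  expect_true(all(rt$ranks$rank[rt$ranks$gene == "B"] == 5.5))
  # per-gene ranks are a permutation with ties averaged: sum is k(k+1)/2
  sums <- tapply(rt$ranks$rank, rt$ranks$gene, sum)
  expect_true(all(sums == k * (k + 1) / 2))
  # above + below + at-median = number of genes for every axis value
  expect_true(all(rt$counts$above_median + rt$counts$below_median +
                    rt$counts$at_median == 2))
  # the all-tied gene is counted in neither direction
  expect_true(all(rt$counts$at_median == 1))
})

test_that("rank analysis excludes genes with missing axis values", {
  d <- tibble::tibble(gene = c("A", "A", "B"), param = c(1, 2, 1),
                      aupr = c(0.1, 0.2, 0.3))
  expect_message(rt <- rank_axis(d), "excluding 1 gene")
  expect_equal(unique(rt$ranks$gene), "A")
})

test_that("aggregation reproduces brute-force group medians, ordered by median", {
  set.seed(5)
  rec <- tibble::tibble(
    gene = rep(letters[1:4], each = 7),
    difference = rnorm(28))
  agg <- aggregate_differences(rec, by = "gene")
  brute <- sort(tapply(rec$difference, rec$gene, median), decreasing = TRUE)
  brute <- setNames(as.numeric(brute), names(brute))
  expect_equal(agg$median, unname(brute))
  expect_equal(agg$gene, names(brute))
  one <- aggregate_differences(rec[1, ], by = "gene")
  expect_equal(one$median, rec$difference[1])
})
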
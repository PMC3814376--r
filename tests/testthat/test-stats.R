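# Statistical kernel: enrichment ratios, exact tests, bootstrap nulls,
# Z-scores, variability scores and moving averages.

test_that("relative_enrichment matches hand arithmetic and edge cases", {
  universe <- sprintf("g%03d", 1:100)
  class_set <- universe[1:20]
  # observed 6 of a 10-gene subset, expected 10 * 20 / 100 = 2
  subset <- c(universe[1:6], universe[50:53])
  r <- relative_enrichment(subset, class_set, universe)
  expect_equal(r$observed, 6)
  expect_equal(r$expected, 2)
  expect_equal(r$ratio, 3)

  expect_equal(relative_enrichment(universe, class_set, universe)$ratio, 1)
  expect_equal(relative_enrichment(universe[30:40], class_set, universe)$ratio, 0)
  expect_error(relative_enrichment(subset, "absent", universe), "Expected")
  expect_error(relative_enrichment("absent", class_set, universe), "universe")
})

test_that("fisher_exact_2x2 agrees with hypergeometric enumeration on all small tables", {
  # hand-checkable cases first
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5))

  # every table with all margins <= 10, against the independent enumeration
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    if (a + b + cc + d == 0) next
    if (a + b > 10 || cc + d > 10 || a + cc > 10 || b + d > 10) next
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    expect_equal(fisher_exact_2x2(tab), fisher_enum(tab), tolerance = 1e-10,
                 info = paste(a, b, cc, d))
  }
})

test_that("fisher_exact_2x2 is transpose-symmetric and validates input", {
  for (i in 1:20) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(t(tab)))
  }
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "zero")
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("bootstrap_enrichment is smoothed, deterministic, and degenerate-safe", {
  universe <- sprintf("g%03d", 1:60)
  # class = universe: every trial ratio is 1, observed 1 -> p = 1
  expect_equal(
    bootstrap_enrichment(10, universe, universe, 1, n_trials = 100, seed = 1), 1)
  p1 <- bootstrap_enrichment(10, universe[1:20], universe, 2.5,
                             n_trials = 200, seed = 99)
  p2 <- bootstrap_enrichment(10, universe[1:20], universe, 2.5,
                             n_trials = 200, seed = 99)
  expect_identical(p1, p2)
  expect_gt(p1, 0) # add-one smoothing: never exactly zero
  p_extreme <- bootstrap_enrichment(10, universe[1:20], universe, 1e6,
                                    n_trials = 100, seed = 1)
  expect_equal(p_extreme, 1 / 101)
})

test_that("wilcoxon_rank_sum reproduces exact enumeration and handles ties", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 2 / 6)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2)), 1)
  expect_equal(wilcoxon_rank_sum(rep(5, 3), rep(5, 4)), 1)
  # tie-free small samples agree with the reference implementation
  set.seed(11)
  for (i in 1:10) {
    a <- sample(1:100, 5); b <- sample(101:200, 6) / 3
    expect_equal(wilcoxon_rank_sum(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample branch against the reference normal approximation
  a <- rnorm(40); b <- rnorm(45, 0.5)
  expect_equal(wilcoxon_rank_sum(a, b),
               stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("wilcoxon_rank_sum detects a one-sd shift in large samples", {
  set.seed(21)
  hits <- vapply(1:100, function(i) {
    a <- rnorm(50, 1); b <- rnorm(500, 0)
    wilcoxon_rank_sum(a, b) < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("zscore uses the population convention and is idempotent", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2))
  x <- rnorm(50, 10, 4)
  expect_equal(zscore(zscore(x)), zscore(x), tolerance = 1e-9)
  expect_equal(mean(zscore(x)), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(zscore(x)^2)), 1, tolerance = 1e-12)
  expect_error(zscore(rep(2, 5)), "variance")
  expect_error(zscore(1), "at least two")
})

test_that("expression_variability trims tails before taking the percentile range", {
  expect_equal(expression_variability(rep(3, 20))$range, 0)

  # independent oracle: manual linear-interpolation percentiles
  manual_q <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  x <- as.numeric(1:100)
  kept <- x[x >= manual_q(x, 0.01) & x <= manual_q(x, 0.99)]
  expected <- abs(manual_q(kept, 0.98) - manual_q(kept, 0.02))
  expect_equal(expression_variability(x)$range, expected, tolerance = 1e-12)

  # trimming blunts a single extreme outlier
  set.seed(5)
  base <- rnorm(200)
  with_outlier <- c(base, 1000)
  delta <- abs(expression_variability(with_outlier)$range -
                 expression_variability(base)$range)
  expect_lt(delta, 1000)
  expect_lt(delta, 1) # the outlier is dropped by the 1% trim entirely
  expect_error(expression_variability(1:5), "at least")
})

test_that("moving_average_by_covariate matches a direct windowed mean", {
  n <- 50L
  expect_equal(moving_average_by_covariate(rep(2, n), rnorm(n), 7)$smoothed,
               rep(2, n))
  y <- rnorm(n)
  expect_equal(moving_average_by_covariate(y, seq_len(n), n)$smoothed,
               rep(mean(y), n))
  # linear y vs covariate stays linear in the interior
  cov <- sort(runif(n))
  y <- 2 * seq_len(n) + 1
  sm <- moving_average_by_covariate(y, cov, 11)$smoothed
  interior <- 6:(n - 5)
  expect_equal(sm[interior], y[interior], tolerance = 1e-9)
  # direct oracle for the sliding-edge windows
  direct <- vapply(seq_len(n), function(i) {
    lo <- max(1, min(i - 5, n - 10)); mean(y[lo:(lo + 10)])
  }, numeric(1))
  expect_equal(sm, direct)
  expect_error(moving_average_by_covariate(y, cov, n + 1), "window")
})
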
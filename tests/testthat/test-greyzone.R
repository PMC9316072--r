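test_that("trapezoidal AUC equals the exhaustive pair-count oracle", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(8:50, 1)
    scores <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) else rnorm(n)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.45))  # both classes guaranteed
    r <- roc_auc(scores, labels, direction = ">")
    expect_equal(r$auc, auc_bruteforce(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random fixtures", {
  skip_if_not_installed("pROC")
  set.seed(55)
  for (i in 1:10) {
    scores <- rnorm(40)
    labels <- c(0, 1, rbinom(38, 1, 0.5))
    ours <- roc_auc(scores, labels, direction = ">")$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(labels, scores, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("AUC honours separation, ties and complement/monotone invariances", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c(1, 1, 0, 0), direction = ">")$auc, 1)
  expect_equal(roc_auc(c(1, 1), c(1, 0), direction = ">")$auc, 0.5)
  set.seed(77)
  for (i in 1:20) {
    scores <- rnorm(30); labels <- c(0, 1, rbinom(28, 1, 0.5))
    a <- roc_auc(scores, labels, direction = ">")$auc
    expect_equal(a + roc_auc(-scores, labels, direction = ">")$auc, 1,
                 tolerance = 1e-12)
    expect_equal(roc_auc(exp(scores), labels, direction = ">")$auc, a,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("sensitivity rises and specificity falls along the curve", {
  set.seed(9)
  r <- roc_auc(rnorm(50), c(0, 1, rbinom(48, 1, 0.4)), direction = ">")
  expect_true(all(diff(r$sensitivity) <= 1e-12))      # along rising threshold
  expect_true(all(diff(1 - r$specificity) <= 1e-12))
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
})

test_that("automatic orientation puts the AUC at or above one half", {
  set.seed(12)
  x <- rnorm(60); y <- c(0, 1, rbinom(58, 1, 0.5))
  r <- roc_auc(x, y)
  expect_gte(r$auc, 0.5)
  r2 <- roc_auc(-x, y)
  expect_equal(r2$auc, r$auc, tolerance = 1e-12)
})

test_that("Youden cutoff matches the exhaustive threshold scan", {
  expect_equal(as.numeric(youden_best_cutoff(c(0, 1, 2, 3), c(0, 0, 1, 1),
                                             direction = ">")), 1.5)
  set.seed(202)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), 1)  # force ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    ours <- youden_best_cutoff(scores, labels, direction = ">")
    oracle <- youden_scan(scores, labels)
    expect_equal(as.numeric(ours), oracle$cutoff)
    expect_equal(attr(ours, "youden_j"), oracle$j, tolerance = 1e-12)
  }
  # degenerate: a single unique score gives J = 0
  deg <- youden_best_cutoff(rep(2, 6), c(1, 1, 1, 0, 0, 0), direction = ">")
  expect_equal(attr(deg, "youden_j"), 0)
})

test_that("bootstrap AUC is seeded, bounded and sane under separation/null", {
  x <- c(10, 11, 12, 0, 1, 2); y <- c(1, 1, 1, 0, 0, 0)
  b <- bootstrap_auc_ci(x, y, B = 200, seed = 1)
  expect_equal(c(b$ci_low, b$ci_high), c(1, 1))
  b2 <- bootstrap_auc_ci(x, y, B = 200, seed = 1)
  expect_identical(b, b2)
  expect_error(bootstrap_auc_ci(x, y, B = 1), "B must be >= 2")
  set.seed(31)
  xn <- rnorm(200); yn <- c(0, 1, rbinom(198, 1, 0.5))
  bn <- bootstrap_auc_ci(xn, yn, B = 400, seed = 2, direction = ">")
  expect_lt(bn$ci_low, 0.5)
  expect_gt(bn$ci_high, 0.5)
})

test_that("grey zone concentrates under separation and widens under the null", {
  set.seed(21)
  x <- c(rnorm(100, 3, 0.1), rnorm(100, 0, 0.1))
  y <- rep(c(1, 0), each = 100)
  gz <- grey_zone(x, y, B = 300, seed = 9)
  expect_gt(gz$grey_zone[1], 1)
  expect_lt(gz$grey_zone[2], 2)
  expect_true(gz$grey_zone[1] <= gz$best_cutoff_mean + 1e-9 &&
                gz$best_cutoff_mean <= gz$grey_zone[2] + 1e-9)
  # label-independent marker: much wider zone than under separation
  xn <- rnorm(200); yn <- rep(c(1, 0), 100)
  gn <- grey_zone(xn, yn, B = 300, seed = 10)
  expect_gt(diff(gn$grey_zone) / diff(range(xn)),
            10 * diff(gz$grey_zone) / diff(range(x)))
  # reproducibility under a fixed seed
  expect_identical(grey_zone(xn, yn, B = 100, seed = 4),
                   grey_zone(xn, yn, B = 100, seed = 4))
})

test_that("grey zone respects marker orientation", {
  set.seed(42)
  x <- c(rnorm(80, 0, 0.4), rnorm(80, 1, 0.4))  # positives LOWER
  y <- rep(c(1, 0), each = 80)
  gz <- grey_zone(x, y, B = 300, seed = 3)
  expect_equal(gz$direction, "<")
  expect_gt(gz$auc_point, 0.8)
  expect_true(gz$grey_zone[1] < 0.5 + 0.3 && gz$grey_zone[2] > 0.5 - 0.3)
})
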
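test_that("leave-two-out splits hold back disjoint subject pairs", {
  ids <- sprintf("S%02d", 1:29)
  sp <- make_ltocv_splits(ids, n_rep = 29, seed = 5)
  expect_length(sp, 29)
  for (s in sp) {
    expect_length(s$test, 2)
    expect_length(s$train, 27)
    expect_length(intersect(s$test, s$train), 0)
  }
  # no duplicate pairs while enough distinct pairs exist
  keys <- vapply(sp, function(s) paste(sort(s$test), collapse = "+"),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
  # 4 subjects, 6 repetitions: all C(4,2) pairs exactly once
  sp4 <- make_ltocv_splits(letters[1:4], n_rep = 6, seed = 1)
  keys4 <- sort(vapply(sp4, function(s) paste(sort(s$test), collapse = "+"),
                       character(1)))
  expect_equal(keys4, c("a+b", "a+c", "a+d", "b+c", "b+d", "c+d"))
  expect_error(make_ltocv_splits(letters[1:3]), "configuration error")
})

test_that("grid expansion follows the step pattern and is capped", {
  spec <- model_spec("rf", grid = list(mtry = c(2, 5, 8)))
  ex <- expand_grid_if_edge(spec, list(mtry = 8))
  expect_true(ex$rerun)
  expect_equal(ex$spec$grid$mtry, c(2, 5, 8, 11, 14))
  # interior choice: untouched
  ex2 <- expand_grid_if_edge(spec, list(mtry = 5))
  expect_false(ex2$rerun)
  expect_equal(ex2$spec$grid$mtry, c(2, 5, 8))
  # geometric axis expands multiplicatively
  sr <- model_spec("svm_radial",
                   grid = list(sigma = 2^c(-9, -8, -7), cost = c(1, 2, 4)))
  ex3 <- expand_grid_if_edge(sr, list(sigma = 2^-9, cost = 2))
  expect_equal(ex3$spec$grid$sigma, 2^c(-11, -10, -9, -8, -7))
  # two expansions exhaust the budget
  s1 <- expand_grid_if_edge(spec, list(mtry = 8))$spec
  s2 <- expand_grid_if_edge(s1, list(mtry = 14))$spec
  expect_warning(ex4 <- expand_grid_if_edge(s2, list(mtry = 20)), "capped")
  expect_false(ex4$rerun)
  # positivity clamp: expanding below a positive bandwidth grid is a no-op
  nb <- model_spec("nb")
  ex5 <- expand_grid_if_edge(nb, list(adjust = 0.5, kernel = TRUE, fL = 1))
  expect_true(all(ex5$spec$grid$adjust > 0))
})

test_that("gaussian naive Bayes posteriors match e1071 on a fixture", {
  set.seed(41)
  n <- 80
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  X <- cbind(a = rnorm(n) + (y == "pos"), b = rnorm(n, sd = 2))
  fit <- ecshock:::.nb_fit(X, y, adjust = 1, kernel = FALSE, fL = 0)
  ours <- ecshock:::.nb_scores(fit, X)
  ref_fit <- e1071::naiveBayes(X, y)
  ref <- predict(ref_fit, X, type = "raw")[, "pos"]
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("kernel naive Bayes trains, scores and separates", {
  set.seed(43)
  n <- 100
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  X <- cbind(a = rnorm(n) + 2.5 * (y == "pos"))
  fit <- ecshock:::.nb_fit(X, y, adjust = 1.5, kernel = TRUE, fL = 1)
  sc <- ecshock:::.nb_scores(fit, X)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(ecshock:::.rank_auc(sc, as.integer(y == "pos")), 0.9)
})

test_that("grid search returns single-point grids unchanged", {
  set.seed(47)
  n <- 60
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 1] <- X[, 1] + 2 * (y == "pos")
  spec <- model_spec("rf", grid = list(mtry = 2), ntree = 50, inner_folds = 3)
  gs <- grid_search(spec, X, y, expand = FALSE)
  expect_equal(gs$pars$mtry, 2)
  expect_true(gs$auc > 0.5)
})

test_that("AUC distribution comparison behaves across regimes", {
  pident <- compare_auc(rep(0.8, 5), rep(0.8, 5))
  expect_equal(as.numeric(pident), 1)
  expect_true(attr(pident, "degenerate"))
  set.seed(53)
  a <- rnorm(29, 0.9, 0.03); b <- rnorm(29, 0.5, 0.03)
  p <- compare_auc(a, b)
  expect_lt(as.numeric(p), 0.001)
  expect_equal(as.numeric(p),
               suppressWarnings(wilcox.test(a, b)$p.value))
  expect_error(compare_auc(0.9, 0.5), "at least 2")
})

test_that("nested cross-validation is reproducible and leak-guarded", {
  coh <- tiny_cohort(6, seed = 83, missingness_rate_echo = 0)
  feats <- cohort_features(coh)
  spec <- model_spec("rf", grid = list(mtry = c(3, 6)), ntree = 60,
                     inner_folds = 3)
  cv1 <- run_nested_cv(spec, feats, n_rep = 3, seed = 11)
  cv2 <- run_nested_cv(spec, feats, n_rep = 3, seed = 11)
  expect_identical(cv1$models$rf$auc, cv2$models$rf$auc)
  expect_length(cv1$models$rf$auc, 3)
  expect_true(all(cv1$models$rf$auc >= 0 & cv1$models$rf$auc <= 1,
                  na.rm = TRUE))
  # outer test subjects never appear in the training sets
  for (s in cv1$splits) expect_length(intersect(s$test, s$train), 0)
  # model features exclude the cuff-vital channels
  expect_false(any(grepl("^d_(sbp|dbp|map)_", unlist(cv1$models$rf$features))))
})
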
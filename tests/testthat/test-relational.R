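# Minimal feature table builder: stages observed per subject, one feature
# column `f_mean`, echo stroke volume `sv_tte_ml`.
fake_features <- function(stages, sv, f = seq_along(stages),
                          sid = "A") {
  data.frame(subject_id = sid, stage = stages, f_mean = f,
             sv_tte_ml = sv, stringsAsFactors = FALSE)
}

test_that("the 20% decrease label is inclusive at the boundary", {
  expect_equal(label_observation(100, c(79, 80, 81)), c(1L, 1L, 0L))
  expect_error(label_observation(-1, 50), "domain error")
  expect_error(label_observation(100, 0), "domain error")
  # invariant to joint rescaling
  set.seed(4)
  for (i in 1:50) {
    r <- runif(1, 50, 150); t <- runif(1, 40, 160); c <- runif(1, 0.1, 10)
    expect_identical(label_observation(r, t), label_observation(c * r, c * t))
  }
})

test_that("count formula matches exhaustive enumeration for T = 1..8", {
  for (T in 1:8) {
    expect_equal(count_relational(1, T), relational_enumerate(T))
  }
  expect_equal(count_relational(30, 5), 330)
  expect_equal(count_relational(29, 5), 319)
  expect_equal(count_relational(1, 1), 1)
  expect_error(count_relational(0, 5))
})

test_that("a fully observed subject yields 11 relational observations", {
  st <- c("baseline", "lbnp15", "lbnp30", "lbnp45", "recovery")
  rel <- build_relational(fake_features(st, c(100, 90, 78, 66, 95)))
  expect_equal(nrow(rel), 11)
  # the singleton relates baseline to itself with zero features, negative
  singleton <- rel[rel$ref_stage == rel$target_stage, ]
  expect_equal(nrow(singleton), 1)
  expect_equal(singleton$ref_stage, "baseline")
  expect_equal(singleton$d_f_mean, 0)
  expect_equal(singleton$label, 0L)
  # labels follow pairwise sv comparison
  r45 <- rel[rel$ref_stage == "baseline" & rel$target_stage == "lbnp45", ]
  expect_equal(r45$label, 1L)  # 66 <= 0.8 * 100
  r1545 <- rel[rel$ref_stage == "lbnp15" & rel$target_stage == "lbnp45", ]
  expect_equal(r1545$label, 1L)  # 66 <= 72
  rrec <- rel[rel$ref_stage == "lbnp45" & rel$target_stage == "recovery", ]
  expect_equal(rrec$label, 0L)
})

test_that("partial observation counts follow 1 + T(T-1)/2", {
  rel3 <- build_relational(
    fake_features(c("baseline", "lbnp30", "recovery"), c(100, 80, 95)))
  expect_equal(nrow(rel3), 4)
  rel1 <- build_relational(fake_features("baseline", 100))
  expect_equal(nrow(rel1), 1)
  # without an observed baseline there is no singleton
  rel_nb <- build_relational(
    fake_features(c("lbnp15", "lbnp45"), c(90, 70)))
  expect_equal(nrow(rel_nb), 1)
  expect_equal(rel_nb$ref_stage, "lbnp15")
})

test_that("relational features are the target-minus-reference differences", {
  st <- c("baseline", "lbnp15", "lbnp30")
  f <- c(0.3, -1.1, 2.0)
  rel <- build_relational(fake_features(st, c(100, 90, 70), f = f))
  pairs <- rel[rel$ref_stage != rel$target_stage, ]
  for (k in seq_len(nrow(pairs))) {
    i <- match(pairs$ref_stage[k], st)
    j <- match(pairs$target_stage[k], st)
    expect_equal(pairs$d_f_mean[k], f[j] - f[i])
  }
  # antisymmetry: swapping roles negates the feature
  d_fwd <- pairs$d_f_mean[pairs$ref_stage == "baseline" &
                            pairs$target_stage == "lbnp30"]
  expect_equal(d_fwd, -(f[1] - f[3]))
})

test_that("missing echo at either endpoint invalidates the observation", {
  st <- c("baseline", "lbnp15", "lbnp30")
  rel <- build_relational(fake_features(st, c(100, NA, 70)))
  expect_equal(nrow(rel), 4)
  bad <- rel$ref_stage == "lbnp15" | rel$target_stage == "lbnp15"
  expect_true(all(!rel$valid[bad]))
  expect_true(all(is.na(rel$label[bad])))
  expect_true(all(rel$valid[!bad]))
})

test_that("ratio markers divide raw target means by reference means", {
  st <- c("baseline", "lbnp45")
  feats <- fake_features(st, c(100, 66))
  raw <- data.frame(subject_id = "A", stage = st, hr_mean = c(60, 72),
                    sv_tte_ml = c(100, 66))
  rel <- build_relational(feats, raw_features = raw)
  pair <- rel[rel$ref_stage != rel$target_stage, ]
  expect_equal(pair$ratio_hr, 72 / 60)
  expect_equal(rel$ratio_hr[rel$ref_stage == rel$target_stage], 1)
})

test_that("duplicate (subject, stage) rows are rejected", {
  f <- fake_features(c("baseline", "baseline"), c(100, 90))
  expect_error(build_relational(f), "data error")
})
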
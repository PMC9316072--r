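test_that("stroke volume from VTI follows CSA x median(VTI)", {
  expect_equal(compute_sv_from_vti(2.0, 20.0), pi * 20, tolerance = 1e-12)
  # median of a symmetric sample
  expect_equal(compute_sv_from_vti(2.0, c(18, 20, 22)), pi * 20,
               tolerance = 1e-12)
  # independent hand computation for nine samples
  set.seed(5)
  vti <- 21 + rnorm(9, 0, 0.5)
  expect_equal(compute_sv_from_vti(2.1, vti),
               pi * (2.1 / 2)^2 * sort(vti)[5], tolerance = 1e-12)
  expect_error(compute_sv_from_vti(2.0, numeric(0)), "domain error")
  expect_error(compute_sv_from_vti(-1, 20), "domain error")
  expect_error(compute_sv_from_vti(0, 20), "domain error")
})

test_that("generator rejects invalid configuration and sizes", {
  m <- ecshock:::.default_multipliers()
  m["sv", 2] <- -0.5
  expect_error(generator_config(stage_multipliers = m), "strictly positive")
  m2 <- ecshock:::.default_multipliers()
  m2["hr", 1] <- 1.1
  expect_error(generator_config(stage_multipliers = m2), "baseline multiplier")
  expect_error(generator_config(missingness_rate_echo = 1), "\\[0, 1\\)")
  expect_error(generate_cohort(0, generator_config()), "domain error")
})

test_that("derived identities hold exactly for every generated beat", {
  coh <- tiny_cohort(4, seed = 7)
  b <- coh$beats
  bsa <- coh$subjects$bsa_m2[match(b$subject_id, coh$subjects$subject_id)]
  expect_lt(max(abs(b$si - b$sv / bsa)), 1e-9)
  expect_lt(max(abs(b$co - b$sv * b$hr / 1000)), 1e-9)
  expect_lt(max(abs(b$ci - b$co / bsa)), 1e-9)
  expect_lt(max(abs(b$str - b$pep / b$lvet)), 1e-9)
  expect_lt(max(abs(b$map - (b$sbp + 2 * b$dbp) / 3)), 1e-9)
  # Bazett: ftc = lvet / sqrt(RR in s); RR reconstructed from HR
  expect_lt(max(abs(b$ftc - b$lvet / sqrt(60 / b$hr))), 1e-9)
  # echo identity: sv_tte = CSA x median(VTI)
  e <- coh$echo[!coh$echo$missing, ]
  vti <- as.matrix(e[, grep("^vti_", names(e))])
  sv <- pi * (e$lvot_diameter_cm / 2)^2 * apply(vti, 1, median)
  expect_lt(max(abs(sv - e$sv_tte_ml)), 1e-9)
})

test_that("beat timestamps are strictly increasing within each stage", {
  coh <- tiny_cohort(3, seed = 9)
  dt <- coh$beats[, list(ok = all(diff(time_s) > 0)),
                  by = c("subject_id", "stage")]
  expect_true(all(dt$ok))
})

test_that("identical config and seed reproduce the cohort bit-identically", {
  c1 <- generate_cohort(5, generator_config(seed = 33))
  c2 <- generate_cohort(5, generator_config(seed = 33))
  expect_identical(c1$beats, c2$beats)
  expect_identical(c1$echo, c2$echo)
  expect_identical(c1$subjects, c2$subjects)
})

test_that("unit multipliers and vanishing noise give a flat cohort", {
  m <- ecshock:::.default_multipliers()
  m[] <- 1
  cfg <- generator_config(stage_multipliers = m, noise_scale = 1e-9,
                          latent_stage_sd = 0, missingness_rate_echo = 0,
                          seed = 2)
  coh <- generate_cohort(1, cfg)
  feats <- cohort_features(coh)
  rel <- relative_changes(feats[c("subject_id", "stage", "sv_mean")],
                          "sv_mean")
  expect_equal(rel$rel_change, rep(1, 5), tolerance = 1e-6)
  rel_tte <- relative_changes(feats[c("subject_id", "stage", "sv_tte_ml")],
                              "sv_tte_ml")
  expect_equal(rel_tte$rel_change, rep(1, 5), tolerance = 1e-6)
})

test_that("with vanishing noise SV-TTE falls strictly with each LBNP step", {
  cfg <- generator_config(noise_scale = 1e-9, missingness_rate_echo = 0,
                          seed = 11)
  coh <- generate_cohort(10, cfg)
  e <- coh$echo
  for (sid in unique(e$subject_id)) {
    sv <- e$sv_tte_ml[e$subject_id == sid][1:4]  # baseline..-45
    expect_true(all(diff(sv) < 0))
  }
})

test_that("echo missingness is seeded, rate-bounded, and leaves beats intact", {
  cfg0 <- generator_config(missingness_rate_echo = 0, seed = 3)
  coh0 <- generate_cohort(4, cfg0)
  expect_identical(inject_missingness(coh0, cfg0)$echo, coh0$echo)

  cfg <- generator_config(missingness_rate_echo = 0.11, seed = 17)
  coh <- generate_cohort(200, cfg)  # 1000 echo entries
  flagged <- sum(coh$echo$missing)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.11)
  expect_gte(flagged, bounds[1])
  expect_lte(flagged, bounds[2])
  expect_true(all(is.na(coh$echo$sv_tte_ml[coh$echo$missing])))
  # beats untouched by echo missingness
  expect_equal(length(unique(paste(coh$beats$subject_id, coh$beats$stage))),
               1000)
  bad <- generator_config()
  bad$missingness_rate_echo <- 1
  expect_error(inject_missingness(coh, bad), "configuration error")
})

test_that("cohort CSV round-trips through the writers", {
  coh <- tiny_cohort(2, seed = 5)
  dir <- withr::local_tempdir()
  write_cohort_csv(coh, dir)
  beats <- data.table::fread(file.path(dir, "beats.csv"))
  expect_equal(nrow(beats), nrow(coh$beats))
  expect_equal(beats$sv, coh$beats$sv, tolerance = 1e-9)
  echo <- utils::read.csv(file.path(dir, "echo.csv"))
  expect_equal(echo$sv_tte_ml, coh$echo$sv_tte_ml, tolerance = 1e-9)
})
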
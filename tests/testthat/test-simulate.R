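test_that("generation is deterministic given config and seed", {
  cfg <- small_config(n = 120)
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cfg, seed = 12)))
  # byte-identical serialization
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(a, f1); write_cohort_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("realized profile counts match the mixing proportions", {
  coh <- generate_cohort(cohort_config(), seed = 5)
  expect_equal(nrow(coh), 4180)
  target <- c(A = 779, B = 749, C = 719, D = 1092, E = 841)
  counts <- table(coh$true_profile)[names(target)]
  p <- target / 4180
  sd3 <- 3 * sqrt(4180 * p * (1 - p))
  expect_true(all(abs(as.integer(counts) - target) <= sd3))
})

test_that("zero-noise scales equal the rounded profile means", {
  cfg <- zero_noise(small_config(n = 150))
  coh <- generate_cohort(cfg, seed = 3)
  for (s in scale_names()) {
    expected <- round(cfg$scale_means[[s]])[coh$true_profile]
    expect_equal(coh[[s]], unname(as.integer(expected)), info = s)
  }
})

test_that("scores stay in 0..6 and TIW is nonnegative under heavy noise", {
  cfg <- small_config(n = 400, rater_bias_sd = 2, rater_noise_sd = 3,
                      patient_noise_sd = 3)
  coh <- generate_cohort(cfg, seed = 9)
  for (s in scale_names())
    expect_true(all(coh[[s]] %in% 0:6), info = s)
  expect_true(all(coh$tiw_days >= 0))
  expect_true(all(coh$delay_hours >= 0))
  expect_true(all(coh$age >= 10))
})

test_that("per-profile feature frequencies are calibrated to the config", {
  cfg <- cohort_config()
  coh <- generate_cohort(cfg, seed = 21)
  viol <- 0L
  for (f in names(cfg$feature_probs)) {
    for (p in cfg$profiles) {
      idx <- coh$true_profile == p
      n_p <- sum(idx)
      prob <- cfg$feature_probs[[f]][[p]]
      tol <- 3 * sqrt(n_p * prob * (1 - prob))
      if (abs(sum(coh[[f]][idx]) - n_p * prob) > max(tol, 1))
        viol <- viol + 1L
    }
  }
  # 3-sigma misses should be rare across 45 x 5 cells (~0.3% each)
  expect_lte(viol, 3L)
})

test_that("a planted TIW slope is recovered by downstream regression", {
  # TIW noise keeps the integer rounding of tiw_days unbiased with respect
  # to the scale; a noiseless plant would carry a small deterministic
  # rounding artifact instead.
  cfg <- small_config(
    n = 4180,
    tiw_coefs = list(intercept = 3, sd = 1.5,
                     coefs = list(pain_assault = 0.68)))
  coh <- generate_cohort(cfg, seed = 4)
  fit <- ols_univariate(coh, "pain_assault")
  expect_lt(abs(fit$beta - 0.68), 0.02)
  # the reported slope equals the closed-form least-squares expression
  x <- coh$pain_assault; y <- coh$tiw_days
  beta_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$beta, beta_cf, tolerance = 1e-12)
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(profile_mixing = c(0.5, 0.2, 0.1, 0.1, 0.2)),
               "sum to 1")
  expect_error(cohort_config(
    tiw_coefs = list(intercept = 0, sd = 1, coefs = list(not_a_scale = 1))),
    "unknown scale name")
  expect_error(cohort_config(rater_bias_sd = -1), "nonnegative")
  expect_error(cohort_config(nonsense_field = 1), "unknown configuration")
})

test_that("configurations and cohorts survive a file round trip", {
  cfg <- small_config(n = 40, n_physicians = 2,
                      caseload_weights = c(0.6, 0.4))
  f <- tempfile(fileext = ".json")
  write_cohort_config(cfg, f)
  cfg2 <- cohort_config(file = f)
  expect_identical(cfg$age_params, cfg2$age_params)
  expect_identical(cfg$profile_mixing, cfg2$profile_mixing)
  expect_identical(cfg$feature_probs, cfg2$feature_probs)
  expect_identical(cfg$caseload_weights, cfg2$caseload_weights)
  coh <- generate_cohort(cfg, seed = 1)
  csv <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, csv)
  coh2 <- read_cohort_csv(csv)
  expect_equal(attr(coh2, "feature_spec"), attr(coh, "feature_spec"))
  expect_equal(coh2$pain_assault, coh$pain_assault)
})

test_that("missingness is MCAR at the requested record rate", {
  cfg <- small_config(n = 300)
  coh <- generate_cohort(cfg, seed = 2)
  expect_identical(apply_missingness(coh, 0, seed = 1), coh)
  all_missing <- apply_missingness(coh, 1, seed = 1)
  n_any <- rowSums(is.na(all_missing[scale_names()]))
  expect_true(all(n_any >= 1))
  # published exclusion load: 1000 of 5180 records incomplete
  big <- generate_cohort(small_config(n = 5180), seed = 8)
  withmiss <- apply_missingness(big, 0.1931, seed = 3)
  affected <- sum(rowSums(is.na(withmiss[scale_names()])) > 0)
  expect_lt(abs(affected - 1000), 3 * sqrt(5180 * 0.1931 * (1 - 0.1931)))
})
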
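test_that("profile descriptives use the interpolated quartile convention", {
  coh <- toy_cohort(data.frame(pain_assault = c(1, 2, 3, 4, 5),
                               tiw_days = 1:5,
                               sleep_disorder = c(1, 0, 0, 1, 0)))
  lab <- setNames(rep("A", 5), coh$patient_id)
  de <- describe_by_profile(coh, lab)
  row <- de$scales[de$scales$profile == "A" &
                     de$scales$scale == "pain_assault", ]
  expect_equal(row$median, 3)
  expect_equal(row$q1, 2)
  expect_equal(row$q3, 4)
  sy <- de$symptoms[de$symptoms$profile == "A", ]
  expect_equal(sy$count, 2)
  expect_equal(sy$percent, 40)
  # constant column: width-zero IQR
  coh2 <- toy_cohort(data.frame(pain_assault = rep(4, 6), tiw_days = 1:6))
  de2 <- describe_by_profile(coh2, setNames(rep("A", 6), coh2$patient_id))
  r2 <- de2$scales[de2$scales$profile == "A", ]
  expect_equal(r2$median, 4); expect_equal(r2$q3 - r2$q1, 0)
})

test_that("a zero-noise cohort reproduces the planted profile medians", {
  cfg <- zero_noise(small_config(n = 600))
  coh <- generate_cohort(cfg, seed = 15)
  de <- describe_by_profile(coh, setNames(coh$true_profile,
                                          coh$patient_id))
  fearE <- de$scales[de$scales$profile == "E" &
                       de$scales$scale == "fear_assault", ]
  expect_equal(fearE$median, 6)
})

test_that("Kruskal-Wallis matches the hand-evaluated rank-sum formula", {
  kt <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kt$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(kt$df, 1)
  same <- kruskal_wallis(list(c(2, 2, 5, 1), c(2, 2, 5, 1)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  flat <- kruskal_wallis(list(rep(3, 5), rep(3, 4)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_raw, 1)
})

test_that("Conover statistics match the hand evaluation and Bonferroni rules", {
  tab <- conover_posthoc(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(abs(tab$statistic), 3.674235, tolerance = 1e-6)
  expect_equal(tab$df, 4)
  same <- conover_posthoc(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_adjusted, 1)
  set.seed(2)
  g3 <- list(sample(0:6, 12, TRUE), sample(0:6, 12, TRUE),
             sample(0:6, 12, TRUE))
  t3 <- conover_posthoc(g3)
  expect_equal(nrow(t3), 3)
  expect_equal(t3$p_adjusted, pmin(1, 3 * t3$p_raw))
  expect_true(all(t3$p_adjusted >= t3$p_raw))
  expect_true(all(t3$p_adjusted <= 1))
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(8)
  groups <- list(sample(0:6, 20, TRUE), sample(0:6, 20, TRUE),
                 sample(0:6, 20, TRUE))
  trans <- lapply(groups, function(x) exp(x / 2) - 1)
  expect_equal(kruskal_wallis(groups)$statistic,
               kruskal_wallis(trans)$statistic, tolerance = 1e-12)
  expect_equal(conover_posthoc(groups)$statistic,
               conover_posthoc(trans)$statistic, tolerance = 1e-12)
})

test_that("univariate OLS matches the closed form", {
  coh <- toy_cohort(data.frame(pain_assault = 0:6, tiw_days = 2 * (0:6)))
  fit <- ols_univariate(coh, "pain_assault")
  expect_equal(fit$beta, 2)
  expect_equal(fit$ci_high - fit$ci_low, 0)
  coh2 <- toy_cohort(data.frame(pain_assault = c(1, 2, 3),
                                tiw_days = c(1, 3, 2)))
  expect_equal(ols_univariate(coh2, "pain_assault")$beta, 0.5)
  coh3 <- toy_cohort(data.frame(pain_assault = rep(3, 5), tiw_days = 1:5))
  expect_error(ols_univariate(coh3, "pain_assault"), "zero variance")
})

test_that("physician comparisons expose case-mix confounding", {
  overall_minus_within <- numeric(8)
  for (r in 1:8) {
    # zero rater bias, but physicians see different profile mixes; fear
    # ratings differ strongly between police-custody (C) and IPV (E) cases
    aff <- matrix(1, 5, 4)
    aff[3, ] <- c(8, 1, 1, 1)   # profile C concentrated on physician 1
    aff[5, ] <- c(1, 1, 1, 8)   # profile E concentrated on physician 4
    cfg <- small_config(n = 1600, n_physicians = 4, rater_bias_sd = 0,
                        profile_affinity = aff)
    coh <- generate_cohort(cfg, seed = 500 + r)
    res <- physician_rating_comparison(
      coh, setNames(coh$true_profile, coh$patient_id), "fear_assault")
    counts <- res$sig_counts
    overall <- counts$n_significant[counts$stratum == "overall"]
    within <- mean(counts$n_significant[counts$stratum != "overall"])
    overall_minus_within[r] <- overall - within
  }
  expect_gt(mean(overall_minus_within), 0)
})

test_that("a physician with a planted bias is flagged within every profile", {
  cfg <- small_config(n = 1500, n_physicians = 3, rater_bias_sd = 0)
  coh <- generate_cohort(cfg, seed = 62)
  biased <- coh$physician_id == "D01"
  coh$pain_assault[biased] <- pmin(coh$pain_assault[biased] + 2L, 6L)
  res <- physician_rating_comparison(
    coh, setNames(coh$true_profile, coh$patient_id), "pain_assault")
  pw <- res$pairwise
  involves <- pw$group_i == "D01" | pw$group_j == "D01"
  for (st in setdiff(unique(pw$stratum), "overall")) {
    sel <- pw$stratum == st & involves
    expect_true(all(pw$p_adjusted[sel] < 0.05), info = st)
  }
})

test_that("identically generated physicians trigger few significant pairs", {
  sig <- 0L; tot <- 0L
  for (r in 1:5) {
    cfg <- small_config(n = 900, n_physicians = 4, rater_bias_sd = 0)
    coh <- generate_cohort(cfg, seed = 700 + r)
    res <- physician_rating_comparison(
      coh, setNames(coh$true_profile, coh$patient_id), "psychosomatic_index")
    counts <- res$sig_counts
    sig <- sig + sum(counts$n_significant)
    tot <- tot + sum(counts$n_pairs)
  }
  # null behavior: about alpha x pairs significant (Bonferroni makes it rarer)
  expect_lt(sig / tot, 0.1)
})
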
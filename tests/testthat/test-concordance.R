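test_that("mid-ranks and tie terms match the reference construction", {
  r <- rank_with_ties(c(0, 1, 1))
  expect_equal(r$ranks, c(1, 2.5, 2.5))
  expect_equal(r$tie_term, 6)
  expect_equal(rank_with_ties(c(3, 1, 2))$tie_term, 0)
  set.seed(5)
  for (i in 1:500) {
    x <- sample(0:6, sample(2:30, 1), replace = TRUE)
    expect_equal(rank_with_ties(x)$ranks, midrank_oracle(x))
  }
  expect_error(rank_with_ties(numeric(0)), "nonempty")
})

test_that("Kendall W behaves at its anchors", {
  expect_equal(kendall_w(cbind(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(kendall_w(cbind(c(1, 2, 3), c(3, 2, 1))), 0)
  expect_equal(kendall_w(cbind(c(0, 1, 1), c(1, 1, 2))), 0.75)
  # both columns constant: undefined, signalled as NA
  expect_true(is.na(kendall_w(cbind(c(1, 1, 1), c(2, 2, 2)))))
})

test_that("W relates to Spearman correlation for two untied raters", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    a <- sample(seq_len(n) * 10)
    b <- sample(seq_len(n) * 10)
    rho <- stats::cor(a, b, method = "spearman")
    expect_lt(abs(kendall_w(cbind(a, b)) - (rho + 1) / 2), 1e-12)
  }
})

test_that("W is rank-based: monotone transforms of a column do not change it", {
  set.seed(3)
  x <- cbind(sample(0:6, 25, TRUE), sample(0:6, 25, TRUE))
  w0 <- kendall_w(x)
  x2 <- x
  x2[, 2] <- exp(x2[, 2]) + 5
  expect_equal(kendall_w(x2), w0)
})

test_that("W under independent uniform scores concentrates near 1/2", {
  set.seed(21)
  ws <- replicate(200, kendall_w(cbind(sample(0:6, 200, TRUE),
                                       sample(0:6, 200, TRUE))))
  expect_lt(abs(mean(ws) - 0.5), 0.05)
})

test_that("interrater matching pairs min counts within shared profiles", {
  coh <- toy_cohort(data.frame(
    physician_id = rep(c("D01", "D02"), c(3, 5)),
    patient_id = sprintf("P%03d", 1:8)))
  lab <- setNames(rep("A", 8), coh$patient_id)
  m <- match_interrater(coh, lab, "D01", "D02", seed = 4)
  expect_equal(nrow(m), 3)
  expect_true(all(m$profile == "A"))
  expect_false(any(duplicated(c(m$id_a, m$id_b))))
  # disjoint profiles: no usable shared profile
  lab2 <- setNames(rep(c("A", "B"), c(3, 5)), coh$patient_id)
  expect_error(match_interrater(coh, lab2, "D01", "D02", seed = 1),
               "share no profile")
})

test_that("interrater bijections are uniform over seeds", {
  coh <- toy_cohort(data.frame(
    physician_id = rep(c("D01", "D02"), each = 2),
    patient_id = c("a1", "a2", "b1", "b2")))
  lab <- setNames(rep("A", 4), coh$patient_id)
  hits <- replicate(2000, {
    m <- match_interrater(coh, lab, "D01", "D02",
                          seed = sample.int(1e7, 1))
    m$id_b[m$id_a == "a1"] == "b1"
  })
  expect_lt(abs(mean(hits) - 0.5), 0.03)
})

test_that("intrarater matching forms disjoint random pairs", {
  coh <- toy_cohort(data.frame(physician_id = rep("D01", 5),
                               patient_id = sprintf("P%03d", 1:5)))
  lab <- setNames(rep("A", 5), coh$patient_id)
  m <- match_intrarater(coh, lab, "D01", seed = 2)
  expect_equal(nrow(m), 2)
  expect_false(any(duplicated(c(m$id_a, m$id_b))))
  m2 <- match_intrarater(coh[1:2, ], lab[1:2], "D01", seed = 2)
  expect_equal(nrow(m2), 1)
  expect_error(match_intrarater(coh[1, ], lab[1], "D01", seed = 1),
               "no profile")
})

test_that("intrarater perfect matchings are uniform over seeds", {
  coh <- toy_cohort(data.frame(physician_id = rep("D01", 4),
                               patient_id = c("p1", "p2", "p3", "p4")))
  lab <- setNames(rep("A", 4), coh$patient_id)
  partner <- replicate(3000, {
    m <- match_intrarater(coh, lab, "D01", seed = sample.int(1e7, 1))
    key <- apply(m, 1, function(r) paste(sort(r[1:2]), collapse = "-"))
    c("p1-p2", "p1-p3", "p1-p4")[c("p1-p2", "p1-p3", "p1-p4") %in% key]
  })
  freq <- table(partner) / 3000
  expect_equal(length(freq), 3L)
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("zero-noise cohorts give perfect pooled concordance", {
  cfg <- zero_noise(small_config(n = 260, n_physicians = 3))
  coh <- generate_cohort(cfg, seed = 6)
  res <- concordance_analysis(coh, setNames(coh$true_profile,
                                            coh$patient_id),
                              "fear_assault", type = "inter", R = 5,
                              seed = 2)
  pooled <- res[res$profile == "pooled", ]
  expect_true(all(pooled$W_mean == 1))
  res_in <- concordance_analysis(coh, setNames(coh$true_profile,
                                               coh$patient_id),
                                 "fear_assault", type = "intra", R = 5,
                                 seed = 2)
  expect_true(all(res_in[res_in$profile == "pooled", "W_mean"] == 1))
})

test_that("pooled W equals the single profile's W when only one profile exists", {
  cfg <- small_config(n = 80, n_physicians = 2,
                      profiles = list("A"), profile_mixing = list(A = 1),
                      feature_probs = lapply(
                        cohort_config()$feature_probs, function(p) p["A"]),
                      scale_means = lapply(
                        cohort_config()$scale_means, function(m) m["A"]),
                      symptom_probs = lapply(
                        cohort_config()$symptom_probs, function(p) p["A"]),
                      age_params = cohort_config()$age_params["A"],
                      delay_params = cohort_config()$delay_params["A"])
  coh <- generate_cohort(cfg, seed = 13)
  res <- concordance_analysis(coh, setNames(coh$true_profile,
                                            coh$patient_id),
                              "pain_assault", type = "inter", R = 3,
                              seed = 9)
  wide <- split(res, res$context)
  for (ctx in wide)
    expect_equal(ctx$W_mean[ctx$profile == "pooled"],
                 ctx$W_mean[ctx$profile == "A"])
})

test_that("missing scale values are excluded pairwise, not silently dropped", {
  cfg <- zero_noise(small_config(n = 120, n_physicians = 2))
  coh <- generate_cohort(cfg, seed = 19)
  coh$pain_assault[seq(1, 120, by = 3)] <- NA
  res <- concordance_analysis(coh, setNames(coh$true_profile,
                                            coh$patient_id),
                              "pain_assault", type = "inter", R = 3,
                              seed = 4)
  expect_true(all(is.na(res$W_mean) | res$W_mean >= 0))
  expect_true(all(res$n_pairs >= 0))
})

test_that("fine-profile sensitivity preserves perfection and granularity helps", {
  cfg <- zero_noise(separable_config(n = 120, p_on = 1, p_off = 0,
                                     n_physicians = 2))
  coh <- generate_cohort(cfg, seed = 41)
  d <- gower_dissimilarity(coh)
  base <- setNames(coh$true_profile, coh$patient_id)
  sens <- sensitivity_fine_profiles(coh, d, base, k_large = 60,
                                    scale = "fear_assault", R = 3, seed = 5)
  expect_equal(sens$k_large, 60)
  pooled_base <- sens$base[sens$base$profile == "pooled", "W_mean"]
  pooled_fine <- sens$fine[sens$fine$profile == "pooled", "W_mean"]
  expect_true(all(pooled_base == 1))
  expect_true(all(pooled_fine == 1))
  # the base run is reproducible from the same seed (seed discipline)
  direct <- concordance_analysis(coh, base, "fear_assault", type = "inter",
                                 R = 3, seed = 5)
  expect_equal(sens$base, direct)
})

test_that("finer typologies do not lose concordance on heterogeneous cohorts", {
  deltas <- numeric(10)
  for (r in 1:10) {
    cfg <- separable_config(n = 150, n_physicians = 2,
                            patient_noise_sd = 1.5, rater_noise_sd = 0.5,
                            rater_bias_sd = 0.2)
    coh <- generate_cohort(cfg, seed = 300 + r)
    d <- gower_dissimilarity(coh)
    base <- setNames(coh$true_profile, coh$patient_id)
    sens <- sensitivity_fine_profiles(coh, d, base, k_large = 30,
                                      scale = "fear_assault", R = 10,
                                      seed = 400 + r)
    deltas[r] <- mean(sens$comparison$delta)
  }
  expect_gte(mean(deltas), -0.02)
})
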
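# Shared fixtures and independent oracles, built in code at test time.

# Small default-structure config.
small_config <- function(n = 200, ...) {
  cohort_config(n_patients = n, ...)
}

# Strongly separated profiles: each profile switches on its own disjoint
# block of features with probability 0.95 and everything else at 0.02, so
# any sensible clustering recovers the planted partition.
separable_config <- function(n = 250, p_on = 0.95, p_off = 0.02, ...) {
  cfg <- cohort_config(n_patients = n, ...)
  feats <- names(cfg$feature_probs)
  blocks <- split(feats, rep_len(seq_along(cfg$profiles), length(feats)))
  for (i in seq_along(cfg$profiles)) {
    p <- cfg$profiles[i]
    for (f in feats) {
      cfg$feature_probs[[f]][p] <- if (f %in% blocks[[i]]) p_on else p_off
    }
  }
  cfg
}

zero_noise <- function(cfg) {
  cfg$rater_bias_sd <- 0
  cfg$rater_noise_sd <- 0
  cfg$patient_noise_sd <- 0
  cfg$tiw_coefs$sd <- 0
  cfg
}

# Independent adjusted Rand index from the contingency-table formula.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) sum(choose(x, 2))
  sij <- ch2(tab)
  si <- ch2(rowSums(tab))
  sj <- ch2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# Exhaustive PAM oracle: best total cost over all medoid subsets.
exhaustive_medoid_cost <- function(D, k) {
  best <- Inf
  for (m in utils::combn(nrow(D), k, simplify = FALSE))
    best <- min(best, sum(apply(D[, m, drop = FALSE], 1, min)))
  best
}

# Sort-based mid-rank oracle, independent of base rank().
midrank_oracle <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# All single-character edits (substitution, deletion, insertion) of a term.
all_single_edits <- function(term) {
  chars <- strsplit(term, "")[[1L]]
  out <- character()
  for (i in seq_along(chars)) {
    out <- c(out, paste(chars[-i], collapse = ""))
    for (l in letters) {
      sub <- chars; sub[i] <- l
      out <- c(out, paste(sub, collapse = ""))
    }
  }
  for (i in 0:length(chars)) for (l in letters)
    out <- c(out, paste(c(chars[seq_len(i)], l,
                          chars[seq_len(length(chars) - i) + i]),
                        collapse = ""))
  unique(out[out != term])
}

# A tiny hand-built cohort for eligibility and gower tests.
toy_cohort <- function(df, spec = NULL) {
  coh <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(coh$patient_id)) coh$patient_id <- sprintf("P%03d", seq_len(nrow(coh)))
  if (!is.null(spec)) attr(coh, "feature_spec") <- spec
  class(coh) <- c("cohort", "data.frame")
  coh
}
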
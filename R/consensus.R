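#' Consensus-resampled PAM over a range of cluster numbers
#'
#' For each candidate number of profiles `k`, draws `n_resamples` subsamples
#' without replacement of size `round(subsample_frac * n)`, runs PAM on the
#' corresponding block of the dissimilarity matrix, and accumulates the
#' consensus matrix: entry (i, j) is the fraction of runs co-sampling i and
#' j in which the pair was co-clustered.  Four stability metrics are
#' computed per k and combined by [select_n_profiles()]:
#'
#' * `pac` -- proportion of ambiguous clustering: the fraction of defined
#'   off-diagonal consensus entries strictly inside `pac_bounds`
#'   (lower is better);
#' * `mean_consensus` -- mean consensus over pairs that a full-data PAM at
#'   the same k places in the same cluster (higher is better);
#' * `jaccard` -- mean, over resampled runs, of the Jaccard similarity
#'   between the run's co-clustered pair set and the full-data partition
#'   restricted to the subsample (higher is better);
#' * `silhouette` -- mean silhouette width of the full-data partition
#'   computed on `1 - consensus`, averaging over defined entries only
#'   (higher is better).
#'
#' Pairs never co-sampled have undefined consensus (`NaN`) and are excluded
#' from every metric.  Each PAM run inside the resampling loop is a single
#' deterministic BUILD+SWAP (resampling already averages out local-search
#' variability).
#'
#' @param dissim Full-cohort dissimilarity matrix, or a cohort (in which
#'   case [gower_dissimilarity()] is applied first).
#' @param k_range Candidate numbers of profiles (default 2--10).
#' @param n_resamples Subsampled clustering runs per k.
#' @param subsample_frac Fraction of the cohort drawn (without replacement)
#'   per run.
#' @param seed Integer master seed; per-run seeds are derived from it and
#'   logged.
#' @param pac_bounds Ambiguity band for the PAC metric.
#' @param keep_matrices Keep the per-k consensus matrices in the result
#'   (default only when `n <= 1500`; metrics are always kept).
#' @return List of class `"consensus_result"`: `metrics` (data frame with
#'   one row per k), `selected_k`, `consensus` (named list of matrices or
#'   `NULL`), `resample_log` (per-run k, seed and subsample size),
#'   `k_range`, `n`, and the call parameters.
#' @seealso [select_n_profiles()], [assign_profiles()]
#' @export
consensus_clustering <- function(dissim, k_range = 2:10, n_resamples = 50L,
                                 subsample_frac = 0.8, seed = 1L,
                                 pac_bounds = c(0.1, 0.9),
                                 keep_matrices = NULL) {
  if (inherits(dissim, "cohort") ||
      (is.data.frame(dissim) && !is.matrix(dissim)))
    dissim <- gower_dissimilarity(dissim)
  d <- as.matrix(dissim)
  n <- nrow(d)
  if (!length(k_range)) stop("k_range must be nonempty", call. = FALSE)
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("subsample_frac must be in (0, 1]", call. = FALSE)
  if (!is_count(n_resamples)) stop("n_resamples must be >= 1", call. = FALSE)
  m <- max(2L, as.integer(round(subsample_frac * n)))
  keep_matrices <- keep_matrices %||% (n <= 1500L)

  # one subsample plan shared across k so candidate k are compared on the
  # same resampling draws
  plan <- with_seed(seed, lapply(seq_len(n_resamples), function(r)
    sort(sample.int(n, m))))

  offdiag <- !diag(TRUE, n)
  metrics <- data.frame()
  consensus_list <- list()
  logs <- list()
  for (k in sort(unique(as.integer(k_range)))) {
    if (k >= n) stop("k_range contains k >= n", call. = FALSE)
    ref <- pam_medoids(d, k, nstart = 1L)
    ref_lab <- unname(ref$labels)
    co_count <- matrix(0, n, n)
    sm_count <- matrix(0, n, n)
    jac <- numeric(n_resamples)
    for (r in seq_len(n_resamples)) {
      idx <- plan[[r]]
      run_seed <- derive_seed(seed, sprintf("consensus-k%d-r%d", k, r))
      fit <- pam_medoids(d[idx, idx], k, nstart = 1L, seed = run_seed)
      lab <- unname(fit$labels)
      sm_count[idx, idx] <- sm_count[idx, idx] + 1
      run_co <- outer(lab, lab, `==`)
      for (cl in seq_len(k)) {
        members <- idx[lab == cl]
        co_count[members, members] <- co_count[members, members] + 1
      }
      ref_co <- outer(ref_lab[idx], ref_lab[idx], `==`)
      off <- !diag(TRUE, length(idx))
      jac[r] <- sum(run_co & ref_co & off) /
        max(1, sum((run_co | ref_co) & off))
      logs[[length(logs) + 1L]] <-
        data.frame(k = k, run = r, seed = run_seed, n_sub = m)
    }
    cons <- co_count / sm_count          # NaN where never co-sampled
    ever <- diag(sm_count) > 0
    diag(cons)[ever] <- 1
    dimnames(cons) <- dimnames(d)
    def <- is.finite(cons) & offdiag
    in_band <- cons > pac_bounds[1L] & cons < pac_bounds[2L]
    pac <- sum(in_band & def) / max(1, sum(def))
    within <- outer(ref_lab, ref_lab, `==`)
    mean_cons <- mean(cons[def & within])
    sil <- consensus_silhouette(cons, ref_lab)
    metrics <- rbind(metrics, data.frame(
      k = k, pac = pac, mean_consensus = mean_cons,
      jaccard = mean(jac), silhouette = sil))
    if (keep_matrices) consensus_list[[as.character(k)]] <- cons
  }
  selected_k <- if (nrow(metrics) == 1L) metrics$k[1L] else
    select_n_profiles(metrics)
  structure(list(metrics = metrics, selected_k = selected_k,
                 consensus = if (keep_matrices) consensus_list,
                 resample_log = do.call(rbind, logs),
                 k_range = sort(unique(as.integer(k_range))), n = n,
                 n_resamples = n_resamples, subsample_frac = subsample_frac,
                 seed = seed, pac_bounds = pac_bounds),
            class = "consensus_result")
}

# Mean silhouette width of `labels` under dissimilarity 1 - consensus,
# averaging a(i) and b(i) over defined (co-sampled) entries only.
#' @noRd
consensus_silhouette <- function(cons, labels) {
  n <- length(labels)
  dd <- 1 - cons
  s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    di <- dd[i, ]
    a <- mean(di[own & is.finite(di)])
    others <- setdiff(unique(labels), labels[i])
    if (!length(others) || !is.finite(a)) next
    b <- suppressWarnings(min(vapply(others, function(cl) {
      mean(di[labels == cl & is.finite(di)])
    }, numeric(1)), na.rm = TRUE))
    if (is.finite(b)) s[i] <- (b - a) / max(a, b)
  }
  mean(s, na.rm = TRUE)
}

#' Choose the number of profiles from consensus metrics
#'
#' Default multimetric rule: rank the candidate k on each stability metric
#' (PAC ascending; mean consensus, Jaccard stability and consensus
#' silhouette descending), then pick the k with the best (lowest) mean
#' rank.  Ties go to the smaller k.  If every metric is constant across
#' candidates the smallest k is returned with a warning.
#'
#' @param metrics Data frame with columns `k`, `pac`, `mean_consensus`,
#'   `jaccard`, `silhouette` (as produced by [consensus_clustering()]).
#' @return The selected k (integer).
#' @export
select_n_profiles <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 2L)
  cols <- c("pac", "mean_consensus", "jaccard", "silhouette")
  missing_cols <- setdiff(cols, names(metrics))
  if (length(missing_cols))
    stop("metrics lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (all(vapply(cols, function(cl)
    length(unique(metrics[[cl]])) == 1L, logical(1)))) {
    warning("all consensus metrics equal across k; returning smallest k")
    return(min(metrics$k))
  }
  ranks <- cbind(
    rank(metrics$pac, ties.method = "average"),
    rank(-metrics$mean_consensus, ties.method = "average"),
    rank(-metrics$jaccard, ties.method = "average"),
    rank(-metrics$silhouette, ties.method = "average"))
  score <- rowMeans(ranks)
  as.integer(metrics$k[order(score, metrics$k)][1L])
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering over k = {%s}: selected k = %d\n",
              paste(x$k_range, collapse = ", "), x$selected_k))
  cat(sprintf("  %d resamples of %.0f%% of n = %d\n", x$n_resamples,
              100 * x$subsample_frac, x$n))
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Final profile assignment and profile summary table
#'
#' Runs PAM at the selected number of profiles on the full dissimilarity
#' matrix, labels profiles `A`, `B`, ... in decreasing cluster-size order,
#' and tabulates each profile the way the typology is usually reported:
#' n, count (%) for every binary situation feature, median (IQR) for the
#' numeric features, and median (IQR) of TIW.
#'
#' @param cohort A cohort data frame.
#' @param dissim Dissimilarity matrix from [gower_dissimilarity()] (computed
#'   from the cohort when `NULL`).
#' @param k Number of profiles (typically `selected_k` of
#'   [consensus_clustering()]).
#' @param nstart,seed Passed to [pam_medoids()].
#' @return List of class `"profile_assignment"`: `clustering` (the
#'   [pam_medoids()] result), `labels` (factor of profile letters named by
#'   patient id) and `summary` (data frame: variable, statistic, one column
#'   per profile plus `All`).
#' @export
assign_profiles <- function(cohort, dissim = NULL, k, nstart = 5L,
                            seed = 1L) {
  d <- dissim %||% gower_dissimilarity(cohort)
  fit <- pam_medoids(d, k, nstart = nstart, seed = seed)
  sizes <- table(fit$labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  tags <- if (k <= 26L) LETTERS[seq_len(k)] else sprintf("P%03d", seq_len(k))
  letter_of <- stats::setNames(tags, names(sizes)[ord])
  labels <- factor(letter_of[as.character(fit$labels)],
                   levels = letter_of[names(sizes)[ord]])
  names(labels) <- names(fit$labels)
  structure(list(clustering = fit, labels = labels,
                 summary = profile_summary(cohort, labels)),
            class = "profile_assignment")
}

#' @noRd
profile_summary <- function(cohort, labels) {
  spec <- feature_spec_of(cohort)
  groups <- c(split(seq_len(nrow(cohort)), labels),
              list(All = seq_len(nrow(cohort))))
  rows <- list()
  add <- function(variable, statistic, vals)
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(variable = variable, statistic = statistic),
      as.data.frame(as.list(vals)))
  add("n", "count", vapply(groups, length, numeric(1)))
  numvars <- c(names(spec)[spec == "numeric"],
               intersect("tiw_days", names(cohort)))
  for (v in names(spec)[spec %in% c("binary", "categorical")]) {
    cnt <- vapply(groups, function(ix)
      sum(cohort[[v]][ix] == 1, na.rm = TRUE), numeric(1))
    pct <- 100 * cnt / vapply(groups, length, numeric(1))
    add(v, "count", cnt)
    add(v, "percent", round(pct, 1))
  }
  for (v in numvars) {
    qs <- vapply(groups, function(ix)
      stats::quantile(cohort[[v]][ix], c(0.5, 0.25, 0.75), na.rm = TRUE,
                      names = FALSE), numeric(3))
    add(v, "median", qs[1L, ])
    add(v, "q1", qs[2L, ])
    add(v, "q3", qs[3L, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
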
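#' Mid-ranks and tie term of a score vector
#'
#' Mid-rank construction used by the tie-corrected Kendall coefficient of
#' concordance: tied values share the average of the ranks they occupy, and
#' the tie term is `T = sum(t^3 - t)` over tie groups of size `t`.
#'
#' @param values Numeric vector (no missing values).
#' @return List with `ranks` and `tie_term`.
#' @examples
#' rank_with_ties(c(0, 1, 1))  # ranks 1, 2.5, 2.5; tie term 6
#' @export
rank_with_ties <- function(values) {
  if (!length(values) || anyNA(values) || any(!is.finite(values)))
    stop("values must be a nonempty vector of finite numbers", call. = FALSE)
  r <- rank(values, ties.method = "average")
  t <- table(values)
  list(ranks = r, tie_term = sum(t^3 - t))
}

#' Tie-corrected Kendall coefficient of concordance
#'
#' For an `n x m` matrix of ordinal scores (n subjects rated by m raters),
#' computes
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum_j T_j},\qquad
#'       S = \sum_i \left(R_i - \frac{m(n+1)}{2}\right)^2,}
#' where `R_i` is the rank sum of subject i over raters (mid-ranks within
#' each rater's column) and `T_j = sum(t^3 - t)` is rater j's tie term.
#' `W` lies in `[0, 1]` (0 = no agreement, 1 = perfect agreement) and
#' reduces to the classical untied formula when all `T_j = 0`.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (`n >= 2`, `m >= 2`, no missing values).
#' @return `W`, or `NA_real_` when the denominator is not positive (e.g. a
#'   rater gave every subject the same score with m = 2), in which case the
#'   statistic is undefined.
#' @examples
#' kendall_w(cbind(c(0, 1, 1), c(1, 1, 2)))  # 0.75
#' @export
kendall_w <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x); m <- ncol(x)
  if (n < 2L || m < 2L) stop("need n >= 2 subjects and m >= 2 raters",
                             call. = FALSE)
  if (anyNA(x)) stop("ratings must be complete", call. = FALSE)
  ranked <- apply(x, 2L, rank_with_ties)
  R <- rowSums(vapply(ranked, `[[`, numeric(n), "ranks"))
  Tsum <- sum(vapply(ranked, `[[`, numeric(1), "tie_term"))
  S <- sum((R - m * (n + 1) / 2)^2)
  denom <- m^2 * (n^3 - n) - m * Tsum
  if (denom <= 0) return(NA_real_)
  12 * S / denom
}

#' Randomly match patients between two physicians within profiles
#'
#' For each violence-situation profile shared by the two physicians, draws
#' equal-size subsamples (the smaller of the two patient counts, sampled
#' without replacement from the larger side) and pairs them by a
#' uniform-random bijection.  Deterministic given `seed`.
#'
#' @param cohort A cohort data frame.
#' @param labels Profile labels, named by `patient_id` (e.g.
#'   `assign_profiles()$labels`) or aligned with the cohort rows.
#' @param physician_a,physician_b Physician identifiers.
#' @param seed Integer seed.
#' @return Data frame of class `"matched_pairs"` with columns `id_a`,
#'   `id_b`, `profile`.
#' @export
match_interrater <- function(cohort, labels, physician_a, physician_b,
                             seed = 1L) {
  lab <- align_labels(cohort, labels)
  ids_a <- split(cohort$patient_id[cohort$physician_id == physician_a],
                 lab[cohort$physician_id == physician_a])
  ids_b <- split(cohort$patient_id[cohort$physician_id == physician_b],
                 lab[cohort$physician_id == physician_b])
  shared <- intersect(names(ids_a)[lengths(ids_a) >= 1L],
                      names(ids_b)[lengths(ids_b) >= 1L])
  if (!any(lengths(ids_a[shared]) >= 2L & lengths(ids_b[shared]) >= 2L))
    stop("physicians ", physician_a, " and ", physician_b,
         " share no profile with >= 2 patients each", call. = FALSE)
  with_seed(seed, {
    pairs <- lapply(shared, function(p) {
      s <- min(length(ids_a[[p]]), length(ids_b[[p]]))
      a <- if (length(ids_a[[p]]) == 1L) ids_a[[p]] else
        sample(ids_a[[p]], s)
      b <- if (length(ids_b[[p]]) == 1L) ids_b[[p]] else
        sample(ids_b[[p]], s)
      data.frame(id_a = a, id_b = b, profile = p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pairs)
  })
  structure(out, class = c("matched_pairs", "data.frame"))
}

#' Randomly pair one physician's patients within profiles
#'
#' For each profile, partitions the physician's patients uniformly at random
#' into disjoint pairs (one patient dropped when the count is odd); the
#' order of pair members is random.  Deterministic given `seed`.
#'
#' @inheritParams match_interrater
#' @param physician Physician identifier.
#' @return Data frame of class `"matched_pairs"` with columns `id_a`,
#'   `id_b`, `profile`.
#' @export
match_intrarater <- function(cohort, labels, physician, seed = 1L) {
  lab <- align_labels(cohort, labels)
  ids <- split(cohort$patient_id[cohort$physician_id == physician],
               lab[cohort$physician_id == physician])
  usable <- names(ids)[lengths(ids) >= 2L]
  if (!length(usable))
    stop("physician ", physician, " has no profile with >= 2 patients",
         call. = FALSE)
  with_seed(seed, {
    pairs <- lapply(usable, function(p) {
      shuffled <- sample(ids[[p]])
      npair <- length(shuffled) %/% 2L
      data.frame(id_a = shuffled[2 * seq_len(npair) - 1L],
                 id_b = shuffled[2 * seq_len(npair)],
                 profile = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pairs)
  })
  structure(out, class = c("matched_pairs", "data.frame"))
}

#' @noRd
align_labels <- function(cohort, labels) {
  if (!is.null(names(labels))) {
    lab <- labels[match(cohort$patient_id, names(labels))]
  } else {
    if (length(labels) != nrow(cohort))
      stop("labels must be named by patient_id or aligned with the cohort",
           call. = FALSE)
    lab <- labels
  }
  if (anyNA(lab)) stop("some patients have no profile label", call. = FALSE)
  as.character(lab)
}

#' Profile-matched concordance of a scale, with repeated random matching
#'
#' For every context (a physician pair for interrater, a single physician
#' for intrarater), repeats the random matching `R` times; each repetition
#' builds the matched `n x 2` ratings matrix (column 1 = first pair members'
#' scores, column 2 = second) and computes the tie-corrected Kendall W per
#' profile and pooled (pairs concatenated across profiles).  Pairs with a
#' missing scale value are excluded pairwise; cells with fewer than 2 usable
#' pairs are reported as `NA` rather than dropped.
#'
#' @param cohort A cohort data frame.
#' @param labels Profile labels (see [match_interrater()]).
#' @param scale Scale column name.
#' @param contexts For `type = "inter"`, a list of 2-vectors of physician
#'   ids (default: all pairs); for `type = "intra"`, a vector of physician
#'   ids (default: all).
#' @param type `"inter"` or `"intra"`.
#' @param R Number of matching repetitions.
#' @param seed Integer master seed; repetition seeds are derived from it.
#' @return Data frame of class `"concordance_result"`, one row per
#'   (context, profile or `"pooled"`): `scale`, `context`, `profile`,
#'   `W_mean`, `W_p2.5`, `W_p97.5` (percentiles over repetitions),
#'   `n_pairs` (mean usable pairs), `R`.
#' @export
concordance_analysis <- function(cohort, labels, scale,
                                 contexts = NULL,
                                 type = c("inter", "intra"),
                                 R = 100L, seed = 1L) {
  type <- match.arg(type)
  if (!scale %in% names(cohort)) stop("unknown scale: ", scale,
                                      call. = FALSE)
  if (!is_count(R)) stop("R must be >= 1", call. = FALSE)
  if (is.null(contexts)) {
    phys <- sort(unique(cohort$physician_id))
    contexts <- if (type == "inter")
      utils::combn(phys, 2L, simplify = FALSE) else as.list(phys)
  }
  scores <- stats::setNames(cohort[[scale]], cohort$patient_id)
  out <- list()
  for (ctx in contexts) {
    ctx_name <- paste(ctx, collapse = ":")
    per_rep <- lapply(seq_len(R), function(r) {
      rep_seed <- derive_seed(seed, sprintf("match-%s-%s-%d",
                                            ctx_name, type, r))
      pairs <- if (type == "inter")
        match_interrater(cohort, labels, ctx[[1L]], ctx[[2L]], rep_seed)
      else match_intrarater(cohort, labels, ctx[[1L]], rep_seed)
      w_of_pairs(pairs, scores)
    })
    cells <- unique(unlist(lapply(per_rep, function(x) x$profile)))
    cells <- c(setdiff(sort(cells), "pooled"), "pooled")
    for (cell in cells) {
      ws <- vapply(per_rep, function(x) {
        i <- match(cell, x$profile)
        if (is.na(i)) NA_real_ else x$W[i]
      }, numeric(1))
      np <- vapply(per_rep, function(x) {
        i <- match(cell, x$profile)
        if (is.na(i)) NA_real_ else x$n_pairs[i]
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        scale = scale, context = ctx_name, profile = cell,
        W_mean = mean(ws, na.rm = TRUE),
        W_p2.5 = stats::quantile(ws, 0.025, na.rm = TRUE, names = FALSE),
        W_p97.5 = stats::quantile(ws, 0.975, na.rm = TRUE, names = FALSE),
        n_pairs = mean(np, na.rm = TRUE), R = R,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("concordance_result", "data.frame"))
}

# Per-profile and pooled W for one realized matching.
#' @noRd
w_of_pairs <- function(pairs, scores) {
  a <- scores[pairs$id_a]
  b <- scores[pairs$id_b]
  usable <- !is.na(a) & !is.na(b)
  cell_w <- function(sel) {
    if (sum(sel) < 2L) return(c(NA_real_, sum(sel)))
    c(kendall_w(cbind(a[sel], b[sel])), sum(sel))
  }
  profs <- sort(unique(pairs$profile))
  per <- vapply(profs, function(p) cell_w(usable & pairs$profile == p),
                numeric(2))
  pooled <- cell_w(usable)
  data.frame(profile = c(profs, "pooled"),
             W = c(per[1L, ], pooled[1L]),
             n_pairs = c(per[2L, ], pooled[2L]),
             stringsAsFactors = FALSE)
}

#' Concordance sensitivity to the granularity of the typology
#'
#' Repeats the concordance analysis after re-assigning profiles at a much
#' larger number of clusters (`k_large`, default `n/5`), so that residual
#' within-profile heterogeneity shrinks; base-k and fine-k runs use the same
#' master seed so differences are attributable to profiling granularity
#' alone.
#'
#' @param cohort A cohort data frame.
#' @param dissim Dissimilarity matrix (computed from the cohort if `NULL`).
#' @param base_labels Profile labels of the base typology.
#' @param k_large Number of fine profiles (`<= n/2`).
#' @param scale,contexts,type,R,seed Passed to [concordance_analysis()].
#' @return List with `base` and `fine` concordance results, `k_large`, and
#'   `comparison` (pooled `W_mean` per context, side by side with the
#'   difference fine - base).
#' @export
sensitivity_fine_profiles <- function(cohort, dissim = NULL, base_labels,
                                      k_large = NULL, scale,
                                      contexts = NULL,
                                      type = c("inter", "intra"),
                                      R = 25L, seed = 1L) {
  type <- match.arg(type)
  n <- nrow(cohort)
  k_large <- as.integer(k_large %||% round(n / 5))
  if (k_large > n %/% 2L)
    stop("k_large must be at most n/2", call. = FALSE)
  d <- dissim %||% gower_dissimilarity(cohort)
  fine <- assign_profiles(cohort, d, k = k_large, nstart = 1L, seed = seed)
  base_res <- concordance_analysis(cohort, base_labels, scale, contexts,
                                   type = type, R = R, seed = seed)
  fine_res <- concordance_analysis(cohort, fine$labels, scale, contexts,
                                   type = type, R = R, seed = seed)
  bp <- base_res[base_res$profile == "pooled", c("context", "W_mean")]
  fp <- fine_res[fine_res$profile == "pooled", c("context", "W_mean")]
  comparison <- merge(bp, fp, by = "context",
                      suffixes = c("_base", "_fine"))
  comparison$delta <- comparison$W_mean_fine - comparison$W_mean_base
  list(base = base_res, fine = fine_res, k_large = k_large,
       comparison = comparison)
}
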
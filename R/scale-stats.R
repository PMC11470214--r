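#' Describe the scales by profile
#'
#' Median and IQR (25th--75th percentiles, linear-interpolation convention)
#' of every scale, per violence-situation profile and overall, plus count
#' (%) of the patient-reported psychological trauma symptom flags -- the
#' usual presentation of the typology's scale table.
#'
#' @param cohort A cohort data frame.
#' @param labels Profile labels (named by patient id or aligned with rows).
#' @return List with data frames `scales` (profile, scale, n, median, q1,
#'   q3) and `symptoms` (profile, symptom, n, count, percent).  Empty cells
#'   are kept with `NA` statistics.
#' @export
describe_by_profile <- function(cohort, labels) {
  lab <- align_labels(cohort, labels)
  groups <- c(split(seq_len(nrow(cohort)), lab),
              list(All = seq_len(nrow(cohort))))
  sc <- intersect(scale_names(), names(cohort))
  scales <- do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(sc, function(s) {
      x <- cohort[[s]][groups[[g]]]
      x <- x[!is.na(x)]
      if (length(x)) {
        q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
        data.frame(profile = g, scale = s, n = length(x),
                   median = q[1L], q1 = q[2L], q3 = q[3L])
      } else {
        data.frame(profile = g, scale = s, n = 0L,
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_)
      }
    }))
  }))
  sy <- intersect(symptom_names(), names(cohort))
  symptoms <- do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(sy, function(s) {
      x <- cohort[[s]][groups[[g]]]
      data.frame(profile = g, symptom = s, n = sum(!is.na(x)),
                 count = sum(x == 1, na.rm = TRUE),
                 percent = round(100 * mean(x == 1, na.rm = TRUE), 1))
    }))
  }))
  rownames(scales) <- rownames(symptoms) <- NULL
  list(scales = scales, symptoms = symptoms)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (delegated to [stats::kruskal.test()]), returned in the package's test
#' result shape so that the Conover post hoc can share the pooled ranking.
#'
#' @param groups A list of numeric vectors (one per group), or a numeric
#'   vector accompanied by `g`.
#' @param g Optional grouping factor when `groups` is a vector.
#' @return List of class `"vioscales_test"`: `statistic` (H), `df`,
#'   `p_raw`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$statistic  # 27/7
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (is.list(groups)) {
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
  } else {
    x <- groups
    g <- factor(g)
  }
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L || length(x) < 3L)
    stop("need >= 2 groups and >= 3 observations", call. = FALSE)
  if (length(unique(x)) == 1L) {
    res <- list(statistic = 0, df = nlevels(g) - 1L, p_raw = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
    res <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                p_raw = kt$p.value)
  }
  structure(res, class = "vioscales_test")
}

#' Conover-Iman pairwise post hoc comparisons
#'
#' Rank-based pairwise comparisons conditional on the Kruskal-Wallis test,
#' sharing its pooled mid-ranking and tie-corrected H: for groups i, j
#' \deqn{t = \frac{\bar R_i - \bar R_j}{\sqrt{S^2 \frac{N-1-H}{N-k}
#'       \left(\frac{1}{n_i}+\frac{1}{n_j}\right)}},\qquad
#'       S^2 = \frac{1}{N-1}\left(\sum_l R_l^2 - N\frac{(N+1)^2}{4}\right),}
#' with two-sided p from Student's t on `N - k` degrees of freedom.
#' Bonferroni adjustment multiplies by the number of pairs (capped at 1).
#'
#' @inheritParams kruskal_wallis
#' @param adjust Apply the Bonferroni correction (default `TRUE`).
#' @return Data frame with one row per group pair: `group_i`, `group_j`,
#'   `statistic` (t), `df`, `p_raw`, `p_adjusted` (`NA` if `adjust =
#'   FALSE`).  When `N - 1 - H <= 0` the statistics are undefined and
#'   returned as `NA` with a warning.
#' @export
conover_posthoc <- function(groups, g = NULL, adjust = TRUE) {
  if (is.list(groups)) {
    x <- unlist(groups, use.names = FALSE)
    gname <- names(groups) %||% as.character(seq_along(groups))
    g <- factor(rep(gname, lengths(groups)), levels = gname)
  } else {
    x <- groups
    g <- factor(g)
  }
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  N <- length(x); k <- nlevels(g)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  H <- kruskal_wallis(split(x, g))$statistic
  r <- rank(x, ties.method = "average")
  rbar <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  pairs <- utils::combn(levels(g), 2L, simplify = FALSE)
  scale_fac <- S2 * (N - 1 - H) / (N - k)
  undefined <- !is.finite(scale_fac) || scale_fac <= 0
  if (undefined && stats::var(r) > 0)
    warning("N - 1 - H <= 0: Conover statistics undefined")
  out <- do.call(rbind, lapply(pairs, function(p) {
    if (undefined) {
      tt <- NA_real_; pv <- NA_real_
    } else {
      se <- sqrt(scale_fac * (1 / n_g[[p[1L]]] + 1 / n_g[[p[2L]]]))
      tt <- (rbar[[p[1L]]] - rbar[[p[2L]]]) / se
      pv <- 2 * stats::pt(-abs(tt), df = N - k)
    }
    data.frame(group_i = p[1L], group_j = p[2L], statistic = tt,
               df = N - k, p_raw = pv, stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- if (adjust) pmin(1, out$p_raw * nrow(out)) else NA_real_
  rownames(out) <- NULL
  out
}

#' Univariate regression of TIW on one scale
#'
#' Ordinary least squares of days of total incapacity to work on a single
#' scale, with the normal-theory 95% confidence interval -- the model used
#' to check that each scale carries information about functional
#' impairment.
#'
#' @param cohort A cohort data frame.
#' @param scale Scale column name.
#' @param outcome Outcome column (default `"tiw_days"`).
#' @param conf_level Confidence level for the slope interval.
#' @return List of class `"vioscales_regression"`: `scale`, `beta` (days of
#'   TIW per scale point), `ci_low`, `ci_high`, `n`.
#' @export
ols_univariate <- function(cohort, scale, outcome = "tiw_days",
                           conf_level = 0.95) {
  x <- cohort[[scale]]; y <- cohort[[outcome]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in scale ", scale,
                               call. = FALSE)
  fit <- stats::lm(y ~ x)
  ci <- if (all(abs(stats::residuals(fit)) < 1e-12))
    c(stats::coef(fit)[2L], stats::coef(fit)[2L])  # exact fit: width 0
  else suppressWarnings(stats::confint(fit, "x", level = conf_level))
  structure(list(scale = scale, beta = unname(stats::coef(fit)[2L]),
                 ci_low = unname(ci[1L]), ci_high = unname(ci[2L]),
                 n = length(x)),
            class = "vioscales_regression")
}

#' @export
print.vioscales_regression <- function(x, ...) {
  cat(sprintf("%s: beta = %.3f (%.3f to %.3f), n = %d\n",
              x$scale, x$beta, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Compare physicians' ratings, overall and within profiles
#'
#' Runs the Kruskal-Wallis test and Bonferroni-adjusted Conover post hoc
#' comparisons of one scale across physicians, first in the overall cohort
#' and then stratified within each violence-situation profile, and counts
#' the physician pairs with a significant adjusted difference.  Comparing
#' the overall count with the within-profile counts shows how much apparent
#' interrater disagreement is explained by case mix.
#'
#' @param cohort A cohort data frame.
#' @param labels Profile labels.
#' @param scale Scale column name.
#' @param alpha Significance level applied to adjusted p values.
#' @return List: `global` (one Kruskal-Wallis result per stratum),
#'   `pairwise` (long data frame of Conover results with a `stratum`
#'   column), `sig_counts` (data frame: stratum, n_pairs, n_significant).
#' @export
physician_rating_comparison <- function(cohort, labels, scale,
                                        alpha = 0.05) {
  lab <- align_labels(cohort, labels)
  strata <- c(list(overall = rep(TRUE, nrow(cohort))),
              lapply(stats::setNames(nm = sort(unique(lab))),
                     function(p) lab == p))
  global <- list(); pw <- list(); counts <- list()
  for (st in names(strata)) {
    sel <- strata[[st]] & !is.na(cohort[[scale]])
    x <- cohort[[scale]][sel]
    g <- droplevels(factor(cohort$physician_id[sel]))
    enough <- names(which(table(g) >= 2L))
    keep <- g %in% enough
    x <- x[keep]; g <- droplevels(g[keep])
    if (nlevels(g) < 2L) next
    global[[st]] <- kruskal_wallis(split(x, g))
    tab <- conover_posthoc(split(x, g))
    tab$stratum <- st
    pw[[st]] <- tab
    counts[[st]] <- data.frame(
      stratum = st, n_pairs = nrow(tab),
      n_significant = sum(tab$p_adjusted < alpha, na.rm = TRUE))
  }
  list(global = global, pairwise = do.call(rbind, pw),
       sig_counts = do.call(rbind, counts))
}
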
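#' Generate a synthetic consultation cohort
#'
#' Draws a cohort of consultation records with the latent structure the
#' downstream analysis assumes: each patient carries a latent
#' violence-situation profile drawn from the mixing proportions; binary
#' situation features are independent Bernoulli draws given the profile; ages
#' and consultation delays come from per-profile log-normal distributions
#' matched to the target median and IQR (ages truncated below `age_min`);
#' each of the nine 0--6 scales is a rounded, clamped latent Gaussian
#' `profile mean + physician bias + patient heterogeneity + rater noise`;
#' days of total incapacity to work (TIW) are a rounded, floored linear
#' function of the realized scale scores.
#'
#' Physician bias is drawn once per (physician, scale) and shared by all of
#' that physician's patients: it is the systematic interrater-disagreement
#' component the concordance analysis is designed to detect.  Patient
#' heterogeneity is drawn once per (patient, scale); rater noise
#' independently per observation.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed; overrides `config$seed`.  The draw is fully
#'   deterministic given the configuration and seed.
#'
#' @return A `data.frame` of class `"cohort"`, one row per patient, with
#'   identifier columns (`patient_id`, `physician_id`), the latent
#'   `true_profile`, numeric `age` and `delay_hours`, 0/1 situation features,
#'   0/1 symptom flags, the nine integer scale columns, `tiw_days`,
#'   `intentional`, `second_evaluation` and an (initially missing)
#'   `certificate_text`.  The attribute `"feature_spec"` maps every
#'   clustering variable to its type (`"binary"` or `"numeric"`) and
#'   `"feature_blocks"` records the table layout of the situation variables.
#' @seealso [render_certificates()], [apply_missingness()],
#'   [gower_dissimilarity()]
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50), seed = 1)
#' table(coh$true_profile)
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "cohort_config"))
    config <- validate_cohort_config(config)
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("a seed is required (config$seed or seed =)",
                          call. = FALSE)
  with_seed(seed, generate_cohort_impl(config))
}

#' @noRd
generate_cohort_impl <- function(config) {
  n <- config$n_patients
  profiles <- config$profiles
  prof <- sample(profiles, n, replace = TRUE, prob = config$profile_mixing)
  pid <- sprintf("P%05d", seq_len(n))

  # physician assignment, optionally profile-dependent (case mix)
  phys_ids <- sprintf("D%02d", seq_len(config$n_physicians))
  if (is.null(config$profile_affinity)) {
    phys <- sample(phys_ids, n, replace = TRUE,
                   prob = config$caseload_weights)
  } else {
    phys <- character(n)
    for (p in profiles) {
      idx <- which(prof == p)
      w <- config$profile_affinity[p, ] * config$caseload_weights
      phys[idx] <- sample(phys_ids, length(idx), replace = TRUE,
                          prob = w / sum(w))
    }
  }

  rlnorm_q <- function(qp, n, lower = NULL) {
    meanlog <- log(qp[["median"]])
    sdlog <- log(qp[["q3"]] / qp[["q1"]]) / (2 * stats::qnorm(0.75))
    if (sdlog <= 0) return(rep(qp[["median"]], n))
    if (is.null(lower)) return(stats::rlnorm(n, meanlog, sdlog))
    # truncate below `lower` by inverse-CDF sampling
    p0 <- stats::plnorm(lower, meanlog, sdlog)
    stats::qlnorm(p0 + stats::runif(n) * (1 - p0), meanlog, sdlog)
  }
  age <- delay <- numeric(n)
  for (p in profiles) {
    idx <- which(prof == p)
    age[idx] <- rlnorm_q(config$age_params[[p]], length(idx),
                         lower = config$age_min %||% 10)
    delay[idx] <- rlnorm_q(config$delay_params[[p]], length(idx))
  }

  draw_binary <- function(problist) {
    out <- lapply(problist, function(pr) {
      x <- integer(n)
      for (p in profiles) {
        idx <- which(prof == p)
        x[idx] <- stats::rbinom(length(idx), 1L, pr[[p]])
      }
      x
    })
    as.data.frame(out)
  }
  features <- draw_binary(config$feature_probs)
  symptoms <- draw_binary(config$symptom_probs)

  # ordinal scales: latent Gaussian, rounded and clamped to {0,...,6}
  scales <- config$scale_means
  bias <- matrix(stats::rnorm(length(phys_ids) * length(scales),
                              sd = config$rater_bias_sd),
                 nrow = length(phys_ids),
                 dimnames = list(phys_ids, names(scales)))
  phys_i <- match(phys, phys_ids)
  scale_df <- as.data.frame(lapply(names(scales), function(s) {
    mu <- unname(scales[[s]][prof])
    latent <- mu + bias[cbind(phys_i, rep(match(s, names(scales)), n))] +
      stats::rnorm(n, sd = config$patient_noise_sd) +
      stats::rnorm(n, sd = config$rater_noise_sd)
    pmin(pmax(as.integer(round(latent)), 0L), 6L)
  }))
  names(scale_df) <- names(scales)

  tc <- config$tiw_coefs
  tiw_lin <- rep(tc$intercept, n)
  for (s in names(tc$coefs)) tiw_lin <- tiw_lin + tc$coefs[[s]] * scale_df[[s]]
  if (tc$sd > 0) tiw_lin <- tiw_lin + stats::rnorm(n, sd = tc$sd)
  tiw <- pmax(as.integer(round(tiw_lin)), 0L)

  coh <- data.frame(
    patient_id = pid, physician_id = phys, true_profile = prof,
    age = age, delay_hours = delay,
    features, symptoms, scale_df, tiw_days = tiw,
    intentional = stats::runif(n) >= config$unintentional_rate,
    second_evaluation = stats::runif(n) < config$second_eval_rate,
    certificate_text = NA_character_,
    stringsAsFactors = FALSE
  )
  clustering_vars <- c("male", "custody", "age", "delay_hours",
                       setdiff(names(config$feature_probs),
                               c("male", "custody")))
  spec <- stats::setNames(
    ifelse(clustering_vars %in% c("age", "delay_hours"), "numeric", "binary"),
    clustering_vars)
  attr(coh, "feature_spec") <- spec
  attr(coh, "feature_blocks") <- config$feature_blocks
  class(coh) <- c("cohort", "data.frame")
  coh
}

#' @noRd
feature_spec_of <- function(cohort) {
  spec <- attr(cohort, "feature_spec")
  if (is.null(spec))
    stop("cohort carries no feature_spec attribute", call. = FALSE)
  missing_cols <- setdiff(names(spec), names(cohort))
  if (length(missing_cols))
    stop("feature_spec names absent from cohort: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  spec
}

#' Blank scale values completely at random
#'
#' Emulates record-level missingness: a fraction `missing_rate` of records is
#' selected (Bernoulli per record, MCAR) and, within each selected record, a
#' random nonempty subset of the nine scale fields is set to `NA`.
#'
#' @param cohort A cohort data frame.
#' @param missing_rate Probability that a record has at least one missing
#'   scale.
#' @param seed Integer seed (deterministic given seed).
#' @param per_scale_prob Probability that each scale of an affected record is
#'   blanked (at least one is always blanked).
#' @return The cohort with `NA`s introduced in scale columns.
#' @export
apply_missingness <- function(cohort, missing_rate, seed,
                              per_scale_prob = 1 / 3) {
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0,1]", call. = FALSE)
  if (missing_rate == 0) return(cohort)
  sc <- intersect(scale_names(), names(cohort))
  with_seed(seed, {
    hit <- which(stats::runif(nrow(cohort)) < missing_rate)
    for (i in hit) {
      blank <- stats::runif(length(sc)) < per_scale_prob
      if (!any(blank)) blank[sample.int(length(sc), 1L)] <- TRUE
      cohort[i, sc[blank]] <- NA_integer_
    }
  })
  cohort
}

#' Write / read a cohort as CSV
#'
#' One row per patient, UTF-8, missing values encoded as empty fields.  The
#' clustering variable types travel in a sidecar JSON written next to the
#' CSV (`<path>.spec.json`) so a round trip preserves the feature spec.
#'
#' @param cohort A cohort data frame.
#' @param path Output CSV path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the cohort.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  spec <- attr(cohort, "feature_spec")
  if (!is.null(spec))
    jsonlite::write_json(
      list(feature_spec = as.list(spec),
           feature_blocks = attr(cohort, "feature_blocks")),
      paste0(path, ".spec.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  coh <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  if (!"certificate_text" %in% names(coh))
    coh$certificate_text <- NA_character_
  specfile <- paste0(path, ".spec.json")
  if (file.exists(specfile)) {
    meta <- jsonlite::read_json(specfile, simplifyVector = TRUE)
    attr(coh, "feature_spec") <- unlist(meta$feature_spec)
    attr(coh, "feature_blocks") <- meta$feature_blocks
  }
  class(coh) <- c("cohort", "data.frame")
  coh
}
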
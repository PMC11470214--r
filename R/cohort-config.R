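#' Scale names used throughout the package
#'
#' The nine 7-level Likert instruments (scored 0--6): three self-rated
#' elements (pain, fear, perception of a life threat), each asked about the
#' assault and about the time of consultation, plus three physician-rated
#' instruments (global functional impairment, quality of the
#' patient--physician interaction, and the psychosomatic index measuring the
#' share of impairment attributable to psychological rather than physical
#' trauma).
#'
#' @return Character vector of the nine scale column names.
#' @export
scale_names <- function() {
  c("pain_assault", "pain_consult", "fear_assault", "fear_consult",
    "threat_assault", "threat_consult", "functional_impairment",
    "interaction_quality", "psychosomatic_index")
}

#' @rdname scale_names
#' @return For `symptom_names()`, the five patient-reported psychological
#'   trauma symptom flags recoverable from certificate text.
#' @export
symptom_names <- function() {
  c("sleep_disorder", "loss_of_appetite", "stress_symptoms",
    "pain_mention", "fear_mention")
}

#' Build (or load) a synthetic-cohort generator configuration
#'
#' The packaged default encodes the study conditions the simulator emulates:
#' five latent violence-situation profiles (A--E) with the published mixing
#' proportions and per-profile binary feature frequencies, per-profile
#' log-normal ages and consultation delays, ordinal scale scores arising from
#' latent profile means plus physician bias, patient heterogeneity and rater
#' noise, and days of total incapacity to work (TIW) generated linearly from
#' scale scores.
#'
#' @param ... Named overrides of the default configuration (see the packaged
#'   file `system.file("extdata", "default_config.json", package =
#'   "vioscales")` for the full field list).  Commonly overridden fields:
#'   `n_patients`, `n_physicians`, `rater_bias_sd`, `rater_noise_sd`,
#'   `patient_noise_sd`, `tiw_coefs`, `missing_rate`, `typo_rate`, `seed`.
#' @param file Optional path to a JSON configuration replacing the packaged
#'   default before overrides are applied.
#'
#' @return A validated list of class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config(n_patients = 100, seed = 1)
#' cfg$profile_mixing
#' @export
cohort_config <- function(..., file = NULL) {
  path <- file %||% system.file("extdata", "default_config.json",
                                package = "vioscales", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration overrides must be named", call. = FALSE)
  unknown <- setdiff(names(over), c(names(cfg), "seed"))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validate_cohort_config(cfg)
}

#' @noRd
validate_cohort_config <- function(cfg) {
  profiles <- as.character(cfg$profiles)
  np <- length(profiles)
  if (np < 1L) stop("at least one profile is required", call. = FALSE)

  mix <- unlist(cfg$profile_mixing)
  if (is.null(names(mix)) || !all(names(mix) %in% profiles))
    names(mix) <- profiles
  check_prob_vector(mix[profiles], "profile_mixing")
  cfg$profile_mixing <- mix[profiles]

  cfg$feature_probs <- lapply(cfg$feature_probs, function(p) {
    p <- unlist(p)
    if (length(p) != np)
      stop("each feature_probs entry needs one probability per profile",
           call. = FALSE)
    if (any(p < 0 | p > 1)) stop("feature_probs must lie in [0,1]",
                                 call. = FALSE)
    names(p) <- profiles
    p
  })
  cfg$scale_means <- lapply(cfg$scale_means, function(m) {
    m <- unlist(m)
    if (any(m < 0 | m > 6))
      stop("scale_means must lie on the 0-6 continuum", call. = FALSE)
    names(m) <- profiles
    m
  })
  if (!setequal(names(cfg$scale_means), scale_names()))
    stop("scale_means must cover exactly the nine scales", call. = FALSE)
  cfg$symptom_probs <- lapply(cfg$symptom_probs, function(p) {
    p <- unlist(p)
    names(p) <- profiles
    p
  })

  for (sd_field in c("rater_bias_sd", "rater_noise_sd", "patient_noise_sd")) {
    v <- cfg[[sd_field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sd_field, " must be a nonnegative number", call. = FALSE)
  }
  for (rate in c("missing_rate", "typo_rate", "unintentional_rate",
                 "second_eval_rate")) {
    v <- cfg[[rate]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(rate, " must be a probability in [0,1]", call. = FALSE)
  }
  if (!is_count(cfg$n_patients)) stop("n_patients must be a positive count",
                                      call. = FALSE)
  if (!is_count(cfg$n_physicians))
    stop("n_physicians must be a positive count", call. = FALSE)

  cw <- unlist(cfg$caseload_weights)
  if (length(cw) != cfg$n_physicians)
    cw <- rep(1 / cfg$n_physicians, cfg$n_physicians)
  check_prob_vector(cw / sum(cw), "caseload_weights")
  cfg$caseload_weights <- cw / sum(cw)

  if (!is.null(cfg$profile_affinity)) {
    aff <- cfg$profile_affinity
    if (is.list(aff) && !is.data.frame(aff))
      aff <- do.call(rbind, lapply(aff, unlist))
    aff <- as.matrix(aff)
    if (nrow(aff) != np || ncol(aff) != cfg$n_physicians)
      stop("profile_affinity must be a (profiles x physicians) weight matrix",
           call. = FALSE)
    if (any(aff < 0) || any(rowSums(aff) <= 0))
      stop("profile_affinity rows must be nonnegative with positive sums",
           call. = FALSE)
    rownames(aff) <- profiles
    cfg$profile_affinity <- aff / rowSums(aff)
  }

  tc <- cfg$tiw_coefs
  coefs <- unlist(tc$coefs)
  bad <- setdiff(names(coefs), scale_names())
  if (length(bad))
    stop("unknown scale name in tiw_coefs: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(tc$sd) || tc$sd < 0)
    stop("tiw_coefs$sd must be nonnegative", call. = FALSE)
  cfg$tiw_coefs <- list(intercept = tc$intercept %||% 0, sd = tc$sd %||% 0,
                        coefs = coefs)

  qpar <- function(x, what) {
    lapply(x, function(q) {
      q <- unlist(q)
      if (!all(c("median", "q1", "q3") %in% names(q)) ||
          q["q1"] > q["median"] || q["median"] > q["q3"] || q["q1"] <= 0)
        stop(what, " needs positive median/q1/q3 per profile", call. = FALSE)
      q
    })
  }
  cfg$age_params <- qpar(cfg$age_params, "age_params")
  cfg$delay_params <- qpar(cfg$delay_params, "delay_params")
  cfg$profiles <- profiles
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @param config A validated `"cohort_config"` object.
#' @param path Output JSON path.
#' @details `write_cohort_config()` serializes a configuration so that
#'   `cohort_config(file = path)` round-trips it exactly (named vectors are
#'   written as JSON objects, not arrays).
#' @export
write_cohort_config <- function(config, path) {
  as_named <- function(x) {
    if (is.list(x) && !is.data.frame(x)) lapply(x, as_named)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  out <- lapply(unclass(config), as_named)
  if (!is.null(config$profile_affinity))
    out$profile_affinity <- apply(config$profile_affinity, 1, as.list,
                                  simplify = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d patients, %d profiles (%s), %d physicians\n",
              x$n_patients, length(x$profiles),
              paste(x$profiles, collapse = ", "), x$n_physicians))
  cat(sprintf("  noise sd: bias %.2f, rater %.2f, patient %.2f\n",
              x$rater_bias_sd, x$rater_noise_sd, x$patient_noise_sd))
  cat(sprintf("  %d binary features, missing_rate %.3f, typo_rate %.2f\n",
              length(x$feature_probs), x$missing_rate, x$typo_rate))
  invisible(x)
}
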
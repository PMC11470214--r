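#' Apply the study eligibility filter
#'
#' Removes, in order: patients younger than 10 years; records of
#' unintentional violence or neglect; consultations more than 30 days (720
#' hours, boundary inclusive on 720) after the incident; patients of
#' physicians with fewer than 300 patients in the loaded cohort (a single
#' study year is assumed, and the volume rule is evaluated on the cohort as
#' loaded); second evaluations; and records with any missing scale value or
#' missing TIW.  A multiply-excludable record is logged under the first rule
#' it trips.
#'
#' @param cohort A cohort data frame.
#' @param min_age Minimum age in years (exclusive below).
#' @param max_delay_hours Maximum delay between incident and consultation.
#' @param min_patients_per_physician Physician volume threshold.
#' @return List: `cohort` (eligible records), `exclusions` (data frame with
#'   rule and n, in application order).
#' @export
apply_eligibility <- function(cohort, min_age = 10,
                              max_delay_hours = 720,
                              min_patients_per_physician = 300) {
  required <- c("age", "intentional", "delay_hours", "physician_id",
                "second_evaluation", "tiw_days")
  absent <- setdiff(required, names(cohort))
  if (length(absent))
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  sc <- intersect(scale_names(), names(cohort))
  volume <- table(cohort$physician_id)
  low_volume <- names(volume)[volume < min_patients_per_physician]
  rules <- list(
    age_below_minimum = cohort$age < min_age,
    unintentional = !cohort$intentional,
    delay_over_30_days = cohort$delay_hours > max_delay_hours,
    low_volume_physician = cohort$physician_id %in% low_volume,
    second_evaluation = as.logical(cohort$second_evaluation),
    incomplete_data = Reduce(`|`, lapply(c(sc, "tiw_days"),
                                         function(v) is.na(cohort[[v]])))
  )
  excluded <- rep(FALSE, nrow(cohort))
  log <- data.frame(rule = names(rules), n = 0L)
  for (i in seq_along(rules)) {
    hit <- rules[[i]] & !excluded
    hit[is.na(hit)] <- FALSE
    log$n[i] <- sum(hit)
    excluded <- excluded | hit
  }
  out <- cohort[!excluded, , drop = FALSE]
  attr(out, "feature_spec") <- attr(cohort, "feature_spec")
  attr(out, "feature_blocks") <- attr(cohort, "feature_blocks")
  list(cohort = out, exclusions = log)
}

#' Run the full study pipeline
#'
#' Orchestrates the two-stage analysis end to end: simulate (or load) the
#' cohort, render and mine certificates, apply eligibility, build the
#' typology (Gower dissimilarity, consensus-resampled PAM, final
#' assignment), characterize the scales (descriptives, physician
#' comparisons, TIW regressions) and measure profile-matched concordance.
#' All stage seeds are derived from one master seed, so a rerun with the
#' same configuration and seed is identical.
#'
#' @param config A [cohort_config()] object (or overrides list) for the
#'   simulated cohort; ignored when `cohort` is supplied.
#' @param seed Master integer seed.
#' @param cohort Optional pre-loaded cohort (skips the simulate stage).
#' @param stages Character vector of stages to run, a subset of
#'   `c("certificates", "mining", "eligibility", "typology", "stats",
#'   "concordance", "sensitivity")`.  Typology is required by the stats and
#'   concordance stages.
#' @param k_range,n_resamples,subsample_frac Consensus-clustering controls.
#' @param concordance_scales Scales analysed in the concordance stage
#'   (default: all nine).
#' @param concordance_R Matching repetitions per context.
#' @param lexicon Lexicon for the certificate stages.
#' @param eligibility_args Named list of overrides for
#'   [apply_eligibility()] (e.g. a lower
#'   `min_patients_per_physician` for small simulated cohorts).
#' @return List of class `"vioscales_run"` with the per-stage outputs
#'   (`cohort`, `exclusions`, `consensus`, `profiles`, `descriptives`,
#'   `regressions`, `physician_comparison`, `concordance_inter`,
#'   `concordance_intra`, `sensitivity`) and a `manifest` recording the
#'   configuration, stage seeds and versions.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         cohort = NULL,
                         stages = c("certificates", "mining", "eligibility",
                                    "typology", "stats", "concordance"),
                         k_range = 2:10, n_resamples = 50L,
                         subsample_frac = 0.8,
                         concordance_scales = scale_names(),
                         concordance_R = 100L,
                         lexicon = default_lexicon(),
                         eligibility_args = list()) {
  stage_seed <- function(label) derive_seed(seed, label)
  manifest <- list(seed = seed, stages = stages,
                   stage_seeds = list(),
                   versions = list(
                     vioscales = as.character(utils::packageVersion("vioscales")),
                     R = R.version.string),
                   timestamp = format(Sys.time(), tz = "UTC"))
  out <- list()
  if (is.null(cohort)) {
    if (!inherits(config, "cohort_config")) config <- cohort_config(config)
    manifest$config <- unclass(config)
    manifest$stage_seeds$simulate <- stage_seed("simulate")
    cohort <- generate_cohort(config, seed = manifest$stage_seeds$simulate)
    if (config$missing_rate > 0) {
      manifest$stage_seeds$missingness <- stage_seed("missingness")
      cohort <- apply_missingness(cohort, config$missing_rate,
                                  manifest$stage_seeds$missingness)
    }
  }
  if ("certificates" %in% stages) {
    manifest$stage_seeds$certificates <- stage_seed("certificates")
    typo <- if (inherits(config, "cohort_config")) config$typo_rate else 0.1
    cohort <- render_certificates(cohort, lexicon, typo_rate = typo,
                                  seed = manifest$stage_seeds$certificates)
  }
  if ("mining" %in% stages) {
    if (all(is.na(cohort$certificate_text))) {
      manifest$mining <- "skipped (no certificate text)"
    } else {
      cohort <- mine_cohort(cohort, lexicon)
    }
  }
  if ("eligibility" %in% stages) {
    elig <- do.call(apply_eligibility, c(list(cohort), eligibility_args))
    cohort <- elig$cohort
    out$exclusions <- elig$exclusions
    if (!nrow(cohort))
      stop("no records remain after the eligibility filter", call. = FALSE)
  }
  out$cohort <- cohort

  if ("typology" %in% stages) {
    d <- gower_dissimilarity(cohort)
    manifest$stage_seeds$consensus <- stage_seed("consensus")
    out$consensus <- consensus_clustering(
      d, k_range = k_range, n_resamples = n_resamples,
      subsample_frac = subsample_frac,
      seed = manifest$stage_seeds$consensus)
    manifest$stage_seeds$assign <- stage_seed("assign")
    out$profiles <- assign_profiles(cohort, d, k = out$consensus$selected_k,
                                    seed = manifest$stage_seeds$assign)
    labels <- out$profiles$labels
  } else labels <- NULL

  if ("stats" %in% stages) {
    if (is.null(labels)) stop("stats stage requires the typology stage",
                              call. = FALSE)
    out$descriptives <- describe_by_profile(cohort, labels)
    out$regressions <- do.call(rbind, lapply(
      intersect(scale_names(), names(cohort)), function(s) {
        r <- ols_univariate(cohort, s)
        data.frame(scale = s, beta = r$beta, ci_low = r$ci_low,
                   ci_high = r$ci_high, n = r$n)
      }))
    out$physician_comparison <- lapply(
      stats::setNames(nm = intersect(scale_names(), names(cohort))),
      function(s) physician_rating_comparison(cohort, labels, s))
  }
  if ("concordance" %in% stages) {
    if (is.null(labels))
      stop("concordance stage requires the typology stage", call. = FALSE)
    manifest$stage_seeds$concordance <- stage_seed("concordance")
    run_conc <- function(type) do.call(rbind, lapply(
      concordance_scales, function(s)
        concordance_analysis(cohort, labels, s, type = type,
                             R = concordance_R,
                             seed = manifest$stage_seeds$concordance)))
    out$concordance_inter <- run_conc("inter")
    out$concordance_intra <- run_conc("intra")
  }
  if ("sensitivity" %in% stages) {
    if (is.null(labels))
      stop("sensitivity stage requires the typology stage", call. = FALSE)
    manifest$stage_seeds$sensitivity <- stage_seed("sensitivity")
    out$sensitivity <- sensitivity_fine_profiles(
      cohort, base_labels = labels,
      scale = concordance_scales[[1L]], R = max(5L, concordance_R %/% 4L),
      seed = manifest$stage_seeds$sensitivity)
  }
  out$manifest <- manifest
  structure(out, class = "vioscales_run")
}

#' Write a pipeline run to a report directory
#'
#' Writes the tabular outputs as CSV, the manifest (with MD5 digests of
#' every written file) as JSON, and a plain-text summary.  Refuses to write
#' into an existing nonempty directory unless `force = TRUE`.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory.
#' @param force Overwrite an existing report.
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop("report directory ", dir, " is not empty; use force = TRUE",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(dir, name), row.names = FALSE, na = "")
    name
  }
  files <- character()
  files <- c(files, wr(as.data.frame(run$cohort), "cohort.csv"))
  if (!is.null(run$exclusions))
    files <- c(files, wr(run$exclusions, "exclusions.csv"))
  if (!is.null(run$consensus))
    files <- c(files, wr(run$consensus$metrics, "consensus_metrics.csv"))
  if (!is.null(run$profiles)) {
    files <- c(files, wr(run$profiles$summary, "profile_summary.csv"))
    files <- c(files, wr(data.frame(
      patient_id = names(run$profiles$labels),
      profile = as.character(run$profiles$labels)), "profile_labels.csv"))
  }
  if (!is.null(run$descriptives)) {
    files <- c(files, wr(run$descriptives$scales, "scales_by_profile.csv"))
    files <- c(files, wr(run$descriptives$symptoms,
                         "symptoms_by_profile.csv"))
  }
  if (!is.null(run$regressions))
    files <- c(files, wr(run$regressions, "tiw_regressions.csv"))
  if (!is.null(run$physician_comparison)) {
    sig <- do.call(rbind, lapply(names(run$physician_comparison),
                                 function(s) cbind(
                                   scale = s,
                                   run$physician_comparison[[s]]$sig_counts)))
    files <- c(files, wr(sig, "physician_significant_pairs.csv"))
  }
  if (!is.null(run$concordance_inter))
    files <- c(files, wr(run$concordance_inter, "concordance_inter.csv"))
  if (!is.null(run$concordance_intra))
    files <- c(files, wr(run$concordance_intra, "concordance_intra.csv"))
  if (!is.null(run$sensitivity))
    files <- c(files, wr(run$sensitivity$comparison,
                         "sensitivity_comparison.csv"))

  digests <- as.list(tools::md5sum(file.path(dir, files)))
  names(digests) <- files
  manifest <- run$manifest
  manifest$file_digests <- digests
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)

  summary_lines <- c(
    "vioscales pipeline report",
    sprintf("seed: %s", manifest$seed),
    sprintf("records analysed: %d", nrow(run$cohort)),
    if (!is.null(run$consensus))
      sprintf("selected number of profiles: %d", run$consensus$selected_k)
    else "typology: skipped",
    if (!is.null(run$concordance_inter)) {
      pooled <- run$concordance_inter[
        run$concordance_inter$profile == "pooled", "W_mean"]
      sprintf("pooled interrater W range: %.2f - %.2f",
              min(pooled, na.rm = TRUE), max(pooled, na.rm = TRUE))
    } else "concordance: skipped",
    if (!is.null(run$regressions))
      sprintf("TIW beta range: %.2f - %.2f", min(run$regressions$beta),
              max(run$regressions$beta))
    else "regressions: skipped")
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.vioscales_run <- function(x, ...) {
  cat("vioscales pipeline run\n")
  cat(sprintf("  cohort: %d records\n", nrow(x$cohort)))
  if (!is.null(x$consensus))
    cat(sprintf("  typology: selected k = %d\n", x$consensus$selected_k))
  if (!is.null(x$concordance_inter)) {
    pooled <- x$concordance_inter[x$concordance_inter$profile == "pooled",
                                  "W_mean"]
    cat(sprintf("  pooled interrater W: %.2f - %.2f\n",
                min(pooled, na.rm = TRUE), max(pooled, na.rm = TRUE)))
  }
  invisible(x)
}
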
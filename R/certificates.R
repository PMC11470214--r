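#' Render synthetic certificate free text
#'
#' Fills `certificate_text` from a simple standardized-certificate sentence
#' template.  For each symptom flag set on a record, one surface term of the
#' corresponding lexicon concept is embedded in a carrier sentence; with
#' probability `typo_rate` the embedded term is corrupted by one random
#' character edit (substitution, insertion or deletion of a letter --
#' whitespace is never touched, so tokenization is preserved).  Records
#' whose flag is unset never contain that concept's terms.
#'
#' @param cohort A cohort data frame with symptom flag columns.
#' @param lexicon A [read_lexicon()] object; every symptom flag present in
#'   the cohort must have a concept with at least one term.
#' @param typo_rate Per-embedded-term corruption probability.
#' @param seed Integer seed (deterministic given seed).
#' @return The cohort with `certificate_text` filled.
#' @export
render_certificates <- function(cohort, lexicon = default_lexicon(),
                                typo_rate = 0.1, seed = 1L) {
  if (!is.numeric(typo_rate) || typo_rate < 0 || typo_rate > 1)
    stop("typo_rate must be in [0,1]", call. = FALSE)
  concepts <- intersect(symptom_names(), names(cohort))
  bad <- setdiff(concepts, names(lexicon))
  if (length(bad))
    stop("no lexicon concept for symptom flag(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (cc in concepts)
    if (!length(lexicon[[cc]]$terms))
      stop("empty lexicon concept: ", cc, call. = FALSE)

  carriers <- c(
    sleep_disorder = "Le sommeil est perturbe avec %s selon le patient.",
    loss_of_appetite = "Il signale une %s depuis les faits.",
    stress_symptoms = "Sont rapportes %s au decours de l agression.",
    pain_mention = "Le patient mentionne %s au moment de l examen.",
    fear_mention = "Il evoque %s en lien avec les faits."
  )
  with_seed(seed, {
    texts <- vapply(seq_len(nrow(cohort)), function(i) {
      parts <- sprintf(
        "Patient de %d ans, examine a la suite d une agression survenue il y a %d heures.",
        as.integer(round(cohort$age[i])),
        as.integer(round(cohort$delay_hours[i])))
      any_flag <- FALSE
      for (cc in concepts) {
        if (is.na(cohort[[cc]][i]) || cohort[[cc]][i] == 0) next
        any_flag <- TRUE
        term <- sample(lexicon[[cc]]$terms, 1L)
        if (stats::runif(1) < typo_rate) term <- typo_one_edit(term)
        carrier <- if (cc %in% names(carriers)) carriers[[cc]] else
          "Il rapporte %s depuis les faits."
        parts <- c(parts, sprintf(carrier, term))
      }
      if (!any_flag)
        parts <- c(parts, "Aucune plainte fonctionnelle signalee ce jour.")
      paste(c(parts, "Examen clinique realise ce jour."), collapse = " ")
    }, character(1))
    cohort$certificate_text <- texts
  })
  cohort
}

# One random character edit on the letters of a term (never on spaces):
# substitution, insertion or deletion, guaranteed to change the string.
#' @noRd
typo_one_edit <- function(term) {
  chars <- strsplit(term, "", fixed = TRUE)[[1L]]
  letter_pos <- which(chars != " ")
  op <- sample(c("sub", "ins", "del"), 1L)
  if (op == "del" && length(letter_pos) <= 1L) op <- "sub"
  if (op == "sub") {
    i <- sample(letter_pos, 1L)
    repl <- sample(setdiff(letters, chars[i]), 1L)
    chars[i] <- repl
  } else if (op == "del") {
    chars <- chars[-sample(letter_pos, 1L)]
  } else {
    i <- sample(letter_pos, 1L)
    chars <- append(chars, sample(letters, 1L), after = i)
  }
  paste(chars, collapse = "")
}
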
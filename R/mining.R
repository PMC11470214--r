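#' Concept lexicons for certificate mining
#'
#' A lexicon maps concept names (symptom flags) to French surface terms plus
#' optional spelling variants.  Surface terms are the forms the certificate
#' generator embeds; both terms and variants are used for matching.  Terms
#' may be multiword; matching then operates on token n-grams.
#'
#' `default_lexicon()` returns the packaged lexicon covering the five
#' patient-reported psychological trauma symptoms (sleep disorders, loss of
#' appetite, stress symptoms, pain, fear); `read_lexicon()` loads a
#' user-supplied JSON file with the same shape
#' (`{"concept": {"terms": [...], "variants": [...]}}`).
#'
#' @param path Path to a lexicon JSON file.
#' @return A named list of class `"lexicon"`; each element has character
#'   vectors `terms` and `variants` (already normalized).
#' @export
read_lexicon <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lex <- lapply(raw, function(entry) {
    if (is.character(entry)) entry <- list(terms = entry)
    terms <- normalize_text(unlist(entry$terms))
    variants <- normalize_text(unlist(entry$variants %||% character()))
    terms <- terms[nzchar(terms)]
    variants <- variants[nzchar(variants)]
    if (!length(terms))
      stop("lexicon concept with no usable term", call. = FALSE)
    list(terms = terms, variants = variants)
  })
  structure(lex, class = "lexicon")
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon_fr.json",
                           package = "vioscales", mustWork = TRUE))
}

#' Normalize free text for lexicon matching
#'
#' Lower-cases, strips French accents and ligatures, collapses punctuation
#' and runs of whitespace to single spaces, and trims.  Idempotent:
#' `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param text Character vector.
#' @return Normalized character vector of the same length.
#' @examples
#' normalize_text("Peur, angoissée...")  # "peur angoissee"
#' @export
normalize_text <- function(text) {
  if (!length(text)) return(character())
  x <- tolower(as.character(text))
  x <- gsub("œ", "oe", x, fixed = TRUE)
  x <- gsub("æ", "ae", x, fixed = TRUE)
  x <- chartr("àâäéèêëîïôöùûüçñ",
              "aaaeeeeiioouuucn", x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

# Length-banded edit-distance tolerance: exact for short tokens (avoids
# false positives like "pour"/"peur"), 1 edit for 5-8 characters, 2 beyond.
#' @noRd
edit_tolerance <- function(term) {
  n <- nchar(term)
  ifelse(n < 5L, 0L, ifelse(n <= 8L, 1L, 2L))
}

#' Fuzzy-match one token against a lexicon concept
#'
#' A token matches if its Levenshtein distance to some term or variant of
#' the concept is within the length-banded tolerance of that term (0 edits
#' below 5 characters, 1 for 5--8, 2 above 8).
#'
#' @param token A single normalized token (or n-gram joined by spaces).
#' @param entry A lexicon concept entry (list with `terms`/`variants`) or a
#'   character vector of terms.
#' @return List with `matched` (logical), `distance` (integer, `NA` if no
#'   match) and `term` (the closest matching term, `NA` if none).
#' @examples
#' match_concept("doulleur", list(terms = "douleur"))  # matched, distance 1
#' @export
match_concept <- function(token, entry) {
  patterns <- if (is.character(entry)) entry
              else c(entry$terms, entry$variants)
  patterns <- normalize_text(patterns)
  d <- utils::adist(token, patterns)[1L, ]
  ok <- d <= edit_tolerance(patterns)
  if (!any(ok)) return(list(matched = FALSE, distance = NA_integer_,
                            term = NA_character_))
  i <- which(ok)[which.min(d[ok])]
  list(matched = TRUE, distance = as.integer(d[i]), term = patterns[i])
}

#' Extract symptom flags from certificate text
#'
#' Tokenizes the normalized text and applies fuzzy concept matching per
#' token (and per n-gram for multiword terms).  A concept flag is set iff at
#' least one token matches one of its terms or variants within the
#' edit-distance policy.  Negation is deliberately not handled: the
#' extraction is a plain term search.
#'
#' @param text A single character string (may be `NA`).
#' @param lexicon A [read_lexicon()] object.
#' @return List with `flags` (named logical vector, one per concept) and
#'   `matches` (data frame: concept, token, term, distance, offset -- the
#'   character offset of the token in the normalized text).
#' @export
extract_features <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "lexicon") || is.list(lexicon))
  flags <- stats::setNames(logical(length(lexicon)), names(lexicon))
  matches <- list()
  norm <- if (length(text) && !is.na(text)) normalize_text(text) else ""
  if (nzchar(norm)) {
    tokens <- strsplit(norm, " ", fixed = TRUE)[[1L]]
    offsets <- c(0L, cumsum(nchar(tokens) + 1L))[seq_along(tokens)] + 1L
    for (concept in names(lexicon)) {
      patterns <- c(lexicon[[concept]]$terms, lexicon[[concept]]$variants)
      for (w in sort(unique(lengths(strsplit(patterns, " ", fixed = TRUE))))) {
        if (length(tokens) < w) next
        grams <- if (w == 1L) tokens else
          vapply(seq_len(length(tokens) - w + 1L), function(i)
            paste(tokens[i:(i + w - 1L)], collapse = " "), character(1))
        pats <- patterns[lengths(strsplit(patterns, " ", fixed = TRUE)) == w]
        d <- utils::adist(grams, pats)
        tol <- edit_tolerance(pats)
        hit <- which(sweep(d, 2L, tol, `<=`), arr.ind = TRUE)
        if (nrow(hit)) {
          flags[concept] <- TRUE
          matches[[length(matches) + 1L]] <- data.frame(
            concept = concept, token = grams[hit[, 1L]],
            term = pats[hit[, 2L]], distance = d[hit],
            offset = offsets[hit[, 1L]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(concept = character(), token = character(),
               term = character(), distance = integer(), offset = integer(),
               stringsAsFactors = FALSE)
  list(flags = flags, matches = matches)
}

#' Mine symptom flags for every record of a cohort
#'
#' Applies [extract_features()] to each record's `certificate_text` and
#' writes the recovered flags into columns named `mined_<concept>`.
#' Records without certificate text get all-`FALSE` flags.
#'
#' @param cohort A cohort data frame with a `certificate_text` column.
#' @param lexicon A [read_lexicon()] object (default: packaged lexicon).
#' @return The cohort with added `mined_*` columns and an attribute
#'   `"match_audit"` (row-bound match data frame with a `patient_id` column).
#' @export
mine_cohort <- function(cohort, lexicon = default_lexicon()) {
  res <- lapply(cohort$certificate_text, extract_features, lexicon = lexicon)
  flags <- do.call(rbind, lapply(res, function(r) r$flags))
  for (concept in names(lexicon))
    cohort[[paste0("mined_", concept)]] <- as.logical(flags[, concept])
  audits <- do.call(rbind, lapply(seq_along(res), function(i) {
    m <- res[[i]]$matches
    if (nrow(m)) cbind(patient_id = cohort$patient_id[i], m) else NULL
  }))
  attr(cohort, "match_audit") <- audits
  cohort
}
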
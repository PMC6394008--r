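#' Lexicons for clinical text normalization
#'
#' Bundles the three lexicons the text pipeline consumes: abbreviation
#' expansions (e.g. `pt` -> `patient`), synonym-to-canonical-concept
#' mappings (e.g. `esophagus` -> `slokdarm`), and the spelling lexicon of
#' valid word forms used by the edit-distance spelling corrector. All
#' entries must be lower-case and the maps must be non-cyclic: no expansion
#' or canonical form may itself be a key.
#'
#' @param abbreviations Named character vector, raw token -> expansion
#'   (expansions may be multi-word).
#' @param synonyms Named character vector, variant -> canonical concept.
#' @param spelling_lexicon Character vector of valid word forms.
#' @return A `lexicon_set`.
#' @export
lexicon_set <- function(abbreviations = character(),
                        synonyms = character(),
                        spelling_lexicon = character()) {
  check_lower <- function(x, what) {
    vals <- c(names(x), unname(x))
    if (any(vals != tolower(vals))) {
      stop(what, " lexicon entries must be lower-case")
    }
  }
  check_lower(abbreviations, "abbreviation")
  check_lower(synonyms, "synonym")
  if (any(spelling_lexicon != tolower(spelling_lexicon))) {
    stop("spelling lexicon entries must be lower-case")
  }
  exp_tokens <- unlist(strsplit(unname(abbreviations), " ", fixed = TRUE))
  if (any(exp_tokens %in% names(abbreviations))) {
    stop("abbreviation map is cyclic: an expansion is itself a key")
  }
  if (any(unname(synonyms) %in% names(synonyms))) {
    stop("synonym map is cyclic: a canonical form is itself a key")
  }
  structure(
    list(abbreviations = abbreviations, synonyms = synonyms,
         spelling_lexicon = unique(spelling_lexicon)),
    class = "lexicon_set"
  )
}

read_tsv_pairs <- function(path) {
  tb <- utils::read.delim(path, header = FALSE, sep = "\t",
                          quote = "", comment.char = "",
                          colClasses = "character", fileEncoding = "UTF-8")
  stats::setNames(tb[[2]], tb[[1]])
}

#' Load the lexicons shipped with the package
#'
#' Small illustrative lexicons (TSV, `key<TAB>value`, lower-case) covering
#' the canonical abbreviation and synonym examples plus the background
#' vocabulary of the synthetic generator; users supply richer ones for real
#' text.
#'
#' @return A [lexicon_set()].
#' @export
default_lexicons <- function() {
  dir <- system.file("extdata", package = "lifehorizon")
  lexicon_set(
    abbreviations = read_tsv_pairs(file.path(dir, "abbreviations.tsv")),
    synonyms = read_tsv_pairs(file.path(dir, "synonyms.tsv")),
    spelling_lexicon = readLines(file.path(dir, "spelling_lexicon.txt"),
                                 encoding = "UTF-8")
  )
}

#' Default letter header/footer patterns
#'
#' @return List with character vectors `header` and `footer` of
#'   case-insensitive line-anchored regular expressions.
#' @export
default_letter_patterns <- function() {
  dir <- system.file("extdata", package = "lifehorizon")
  tb <- utils::read.delim(file.path(dir, "letter_patterns.tsv"),
                          header = FALSE, sep = "\t", quote = "",
                          colClasses = "character", fileEncoding = "UTF-8")
  list(header = tb[[2]][tb[[1]] == "header"],
       footer = tb[[2]][tb[[1]] == "footer"])
}

match_any <- function(lines, patterns) {
  hit <- rep(FALSE, length(lines))
  for (p in patterns) {
    hit <- hit | grepl(p, lines, ignore.case = TRUE, perl = TRUE)
  }
  hit
}

#' Remove letter boilerplate
#'
#' Letters carry greeting/address header blocks and signature footers that
#' hold no prognostic content. Leading lines matching a header pattern are
#' dropped; everything from the first footer-matching line onward is
#' dropped. Notes are returned unchanged.
#'
#' @param text Document text (lines separated by newlines).
#' @param doc_type `"note"` or `"letter"`.
#' @param patterns Header/footer regexes as from
#'   [default_letter_patterns()].
#' @return The stripped text.
#' @export
strip_boilerplate <- function(text, doc_type,
                              patterns = default_letter_patterns()) {
  if (doc_type != "letter" || !nzchar(text)) {
    return(text)
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  is_header <- match_any(lines, patterns$header)
  keep_from <- 1L
  while (keep_from <= length(lines) &&
         (is_header[keep_from] || !nzchar(trimws(lines[keep_from])))) {
    keep_from <- keep_from + 1L
  }
  is_footer <- match_any(lines, patterns$footer)
  footer_at <- which(is_footer & seq_along(lines) >= keep_from)
  keep_to <- if (length(footer_at) > 0) footer_at[1] - 1L else length(lines)
  if (keep_from > keep_to) {
    return("")
  }
  lines <- lines[keep_from:keep_to]
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  paste(lines, collapse = "\n")
}

#' Lower-case and tokenize text
#'
#' Lower-cases, splits punctuation from words, and drops formatting noise
#' (repeated separators, markup remnants). Tokens are maximal runs of
#' alphanumeric characters; order is preserved.
#'
#' @param text A character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
normalize_tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(character())
  }
  stringr::str_extract_all(stringr::str_to_lower(text), "[[:alnum:]]+")[[1]]
}

#' Expand abbreviations
#'
#' Replaces each token that is a key of the abbreviation lexicon by its
#' expansion; multi-word expansions are spliced in order.
#'
#' @param tokens Lower-cased tokens.
#' @param lexicons A [lexicon_set()].
#' @return Token vector with abbreviations expanded.
#' @export
expand_abbreviations <- function(tokens, lexicons) {
  if (length(tokens) == 0) return(character())
  hit <- tokens %in% names(lexicons$abbreviations)
  if (!any(hit)) return(tokens)
  out <- as.list(tokens)
  out[hit] <- strsplit(unname(lexicons$abbreviations[tokens[hit]]), " ",
                       fixed = TRUE)
  unlist(out, use.names = FALSE)
}

#' Map synonym variants to canonical concepts
#'
#' Idempotent: canonical forms are fixed points of the mapping.
#'
#' @inheritParams expand_abbreviations
#' @return Token vector with variants canonicalized.
#' @export
map_synonyms <- function(tokens, lexicons) {
  if (length(tokens) == 0) return(character())
  hit <- tokens %in% names(lexicons$synonyms)
  tokens[hit] <- unname(lexicons$synonyms[tokens[hit]])
  tokens
}

#' Correct spelling against a lexicon
#'
#' A token absent from the spelling lexicon is replaced by the unique
#' lexicon word within `max_edit_distance` (Levenshtein). When zero or
#' several lexicon words tie at the minimal distance the token is left
#' unchanged — a conservative no-change tie-break.
#'
#' @inheritParams expand_abbreviations
#' @param max_edit_distance Maximum Levenshtein distance considered.
#' @return Token vector with unambiguous misspellings corrected.
#' @export
correct_spelling <- function(tokens, lexicons, max_edit_distance = 1L) {
  stopifnot(max_edit_distance >= 1)
  if (length(tokens) == 0 || length(lexicons$spelling_lexicon) == 0) {
    return(tokens)
  }
  oov <- setdiff(unique(tokens), lexicons$spelling_lexicon)
  if (length(oov) == 0) return(tokens)
  d <- utils::adist(oov, lexicons$spelling_lexicon)
  repl <- vapply(seq_along(oov), function(i) {
    dmin <- min(d[i, ])
    if (dmin > max_edit_distance) return(oov[i])
    cand <- which(d[i, ] == dmin)
    if (length(cand) == 1L) lexicons$spelling_lexicon[cand] else oov[i]
  }, "")
  names(repl) <- oov
  hit <- tokens %in% oov
  tokens[hit] <- unname(repl[tokens[hit]])
  tokens
}

#' Run the full text pipeline on one document
#'
#' Composition, in order: boilerplate stripping, normalization and
#' tokenization, abbreviation expansion, synonym mapping, spelling
#' correction, then the optional annotator hook (e.g. a lemmatizer; the
#' default is pass-through). The composed pipeline is idempotent on its own
#' output given well-formed lexicons.
#'
#' @param text Document text.
#' @param doc_type `"note"` or `"letter"`.
#' @param month Death-anchored month index 1..61 (61 = month of death).
#' @param lexicons A [lexicon_set()].
#' @param patterns Letter boilerplate patterns.
#' @param annotator Optional function `tokens -> tokens`.
#' @param max_edit_distance Passed to [correct_spelling()].
#' @return A one-row tibble `(doc_type, source_month, tokens)` with a
#'   list-column of tokens.
#' @export
preprocess_document <- function(text, doc_type, month,
                                lexicons = default_lexicons(),
                                patterns = default_letter_patterns(),
                                annotator = NULL,
                                max_edit_distance = 1L) {
  stopifnot(month >= 1, month <= 61)
  tokens <- strip_boilerplate(text, doc_type, patterns) |>
    normalize_tokenize() |>
    expand_abbreviations(lexicons) |>
    map_synonyms(lexicons) |>
    correct_spelling(lexicons, max_edit_distance)
  if (!is.null(annotator)) {
    tokens <- annotator(tokens)
  }
  tibble(doc_type = doc_type, source_month = as.integer(month),
         tokens = list(tokens))
}

#' Preprocess every document in a cohort
#'
#' Applies [preprocess_document()] to all notes and letters, attaching the
#' death-anchored month index of the consultation each document belongs to.
#'
#' @param cohort An `emr_cohort`.
#' @inheritParams preprocess_document
#' @return Tibble `(patient_id, consult_id, doc_type, source_month, tokens)`.
#' @export
preprocess_cohort <- function(cohort,
                              lexicons = default_lexicons(),
                              patterns = default_letter_patterns(),
                              annotator = NULL,
                              max_edit_distance = 1L) {
  docs <- cohort$documents |>
    dplyr::inner_join(cohort$consultations[c("consult_id", "patient_id", "date")],
                      by = "consult_id") |>
    dplyr::inner_join(cohort$patients[c("patient_id", "death_date")],
                      by = "patient_id")
  month <- month_index(docs$date, docs$death_date)
  tokens <- vector("list", nrow(docs))
  for (i in seq_len(nrow(docs))) {
    tokens[[i]] <- strip_boilerplate(docs$text[i], docs$doc_type[i],
                                     patterns) |>
      normalize_tokenize() |>
      expand_abbreviations(lexicons) |>
      map_synonyms(lexicons) |>
      correct_spelling(lexicons, max_edit_distance)
    if (!is.null(annotator)) {
      tokens[[i]] <- annotator(tokens[[i]])
    }
  }
  tibble(
    patient_id = docs$patient_id,
    consult_id = docs$consult_id,
    doc_type = docs$doc_type,
    source_month = month,
    tokens = tokens
  )
}

# Death-anchored month index: 61 = the 30 days ending at death, 1 = earliest.
month_index <- function(date, death_date) {
  days_before <- as.integer(death_date - date)
  m <- 61L - days_before %/% 30L
  if (any(m < 1L | m > 61L)) {
    stop("event date outside the 61-month history window")
  }
  m
}
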
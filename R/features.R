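FEATURE_CATEGORIES <- c(
  "diagnosis_icpc", "reason_for_encounter_icpc", "icd",
  "intervention_icpc", "medical_history_icpc",
  "medication", "lab", "consultation_type"
)
ABSTRACTION_LEVELS <- c("full", "letter_number", "letter",
                        "element", "letter_element")
CUTOFF_METHODS <- c("none", "absolute_100", "relative_1pct",
                    "bottom_25pct_coverage")

#' Thematic element lookup for ICPC numeric components
#'
#' Editable mapping from the numeric component of an ICPC-style code to a
#' broad thematic consultation element (e.g. numbers 30-49 are standard
#' procedures), shipped as a TSV of inclusive ranges.
#'
#' @return Tibble `(from, to, element)`.
#' @export
default_element_table <- function() {
  path <- system.file("extdata", "icpc_elements.tsv", package = "lifehorizon")
  as_tibble(utils::read.delim(path, sep = "\t", colClasses =
                                c("integer", "integer", "character")))
}

#' Abstract a clinical code
#'
#' ICPC/ICD codes of form `[letter][number].[decimals]` can be simplified
#' to coarser abstraction levels: `full` keeps the code, `letter_number`
#' drops the decimals (D84.02 -> D84), `letter` keeps the body-system
#' letter (D), `element` maps the numeric component to a thematic
#' consultation element, and `letter_element` combines both
#' (D+standard procedure).
#'
#' @param code Character vector of codes matching the code pattern.
#' @param level One of `r paste(ABSTRACTION_LEVELS, collapse = ", ")`.
#' @param element_table Range lookup as from [default_element_table()];
#'   a code whose numeric component falls in no range is a mapping error.
#' @return Character vector of abstracted feature strings.
#' @export
abstract_code <- function(code, level, element_table = default_element_table()) {
  level <- match.arg(tolower(level), ABSTRACTION_LEVELS)
  bad <- !grepl(CODE_PATTERN, code)
  if (any(bad)) {
    stop("malformed clinical code(s): ", paste(unique(code[bad]), collapse = ", "))
  }
  if (level == "full") return(code)
  letter <- substr(code, 1, 1)
  number <- as.integer(sub("\\..*$", "", substr(code, 2, nchar(code))))
  if (level == "letter_number") {
    return(paste0(letter, number))
  }
  if (level == "letter") {
    return(letter)
  }
  idx <- vapply(number, function(nm) {
    hit <- which(element_table$from <= nm & element_table$to >= nm)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, 1L)
  if (anyNA(idx)) {
    stop("no thematic element for code(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "))
  }
  element <- element_table$element[idx]
  if (level == "element") element else paste0(letter, "+", element)
}

#' Strip dosage and usage text from a medication entry
#'
#' Medication strings carry dosage (e.g. `500mg`) and usage (`3dd`) text
#' irrelevant to featurization; the leading drug-name token(s) are kept.
#'
#' @param raw Character vector of raw medication strings.
#' @return Cleaned drug names, lower-cased and trimmed.
#' @export
clean_medication <- function(raw) {
  dose_pattern <- paste0(
    "^([0-9]+([.,][0-9]+)?(mg|mcg|ug|g|ml|ie|e|iu)?|[0-9]+(dd|x)|",
    "dd|zn|po|iv|sc|per|dag|daags|tablet|tabletten|capsule|capsules|",
    "druppels|zalf|creme)$"
  )
  vapply(stringr::str_to_lower(trimws(raw)), function(s) {
    toks <- strsplit(s, "[[:space:]]+")[[1]]
    cut <- which(grepl(dose_pattern, toks))
    if (length(cut) > 0) toks <- toks[seq_len(cut[1] - 1L)]
    paste(toks, collapse = " ")
  }, "", USE.NAMES = FALSE)
}

#' Should a lab result be featurized?
#'
#' Lab tests enter the feature set only when they produced an irregular or
#' abnormal value; normal results are uninformative for prognosis and are
#' dropped.
#'
#' @param flag Character vector of lab flags.
#' @return Logical vector, `TRUE` for irregular/abnormal.
#' @export
filter_lab <- function(flag) {
  flag %in% c("irregular", "abnormal")
}

#' Apply a frequency cut-off to a feature count table
#'
#' Four cut-off rules: `none` keeps everything; `absolute_100` keeps
#' features occurring at least 100 times in the corpus; `relative_1pct`
#' keeps features whose share of their category's token mass is at least
#' 1%; `bottom_25pct_coverage` drops the least frequent features that
#' together account for at most 25% of the category token mass (among tied
#' counts the lexicographically smaller feature is kept longest).
#'
#' @param feature_counts Named non-negative numeric vector of corpus counts
#'   for one feature category.
#' @param method One of `r paste(CUTOFF_METHODS, collapse = ", ")`.
#' @return Character vector of retained feature names, sorted.
#' @export
apply_cutoff <- function(feature_counts, method) {
  method <- match.arg(tolower(method), CUTOFF_METHODS)
  stopifnot(all(feature_counts >= 0))
  if (length(feature_counts) == 0) return(character())
  nm <- names(feature_counts)
  keep <- switch(
    method,
    none = nm,
    absolute_100 = nm[feature_counts >= 100],
    relative_1pct = nm[feature_counts / sum(feature_counts) >= 0.01],
    bottom_25pct_coverage = {
      # drop order: ascending count; among ties drop the larger name first
      ord <- order(feature_counts, -rank(nm), decreasing = FALSE)
      cum <- cumsum(feature_counts[ord])
      drop <- ord[cum <= 0.25 * sum(feature_counts)]
      setdiff(nm, nm[drop])
    }
  )
  sort(keep)
}

#' Per-category feature configuration
#'
#' The default reproduces the best-performing representation of the study
#' this package models: diagnosis, reason-for-encounter and ICD codes
#' abstracted to `[letter][number]`; intervention and medical-history codes
#' to `letter+element`; medication names cleaned of dosage; labs restricted
#' to irregular/abnormal results; and the absolute-occurrence-below-100
#' cut-off everywhere.
#'
#' @param abstraction Named character vector of abstraction levels for the
#'   five coded-event categories.
#' @param cutoff Named character vector of cut-off methods for all 8
#'   categories.
#' @return A `feature_config` list.
#' @export
feature_config <- function(abstraction = c(diagnosis_icpc = "letter_number",
                                           reason_for_encounter_icpc = "letter_number",
                                           icd = "letter_number",
                                           intervention_icpc = "letter_element",
                                           medical_history_icpc = "letter_element"),
                           cutoff = stats::setNames(
                             rep("absolute_100", length(FEATURE_CATEGORIES)),
                             FEATURE_CATEGORIES)) {
  missing_abs <- setdiff(EVENT_CATEGORIES, names(abstraction))
  if (length(missing_abs) > 0) {
    stop("abstraction level missing for: ", paste(missing_abs, collapse = ", "))
  }
  missing_cut <- setdiff(FEATURE_CATEGORIES, names(cutoff))
  if (length(missing_cut) > 0) {
    stop("cut-off method missing for: ", paste(missing_cut, collapse = ", "))
  }
  structure(list(abstraction = abstraction, cutoff = cutoff),
            class = "feature_config")
}

#' @rdname feature_config
#' @export
default_feature_config <- function() feature_config()

# One row per featurized occurrence: (consult_id, category, feature).
featurize_occurrences <- function(cohort, config,
                                  element_table = default_element_table()) {
  ev <- cohort$events
  ev_feat <- if (nrow(ev) == 0) {
    tibble(consult_id = integer(), category = character(),
           feature = character())
  } else ev |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(feature = abstract_code(
      .data$code, config$abstraction[[dplyr::cur_group()$category]],
      element_table)) |>
    dplyr::ungroup() |>
    dplyr::select("consult_id", "category", "feature")
  med <- tibble(
    consult_id = cohort$medications$consult_id,
    category = "medication",
    feature = clean_medication(cohort$medications$medication)
  )
  lb <- cohort$labs[filter_lab(cohort$labs$flag), ]
  lab <- tibble(consult_id = lb$consult_id, category = "lab",
                feature = lb$lab_code)
  ct <- tibble(consult_id = cohort$consultations$consult_id,
               category = "consultation_type",
               feature = cohort$consultations$consultation_type)
  dplyr::bind_rows(ev_feat, med, lab, ct)
}

#' Build the feature vocabulary of a cohort
#'
#' Features are abstracted per the configuration, counted over the whole
#' cohort, and filtered by the per-category cut-off. The resulting
#' vocabulary fixes every feature's vector position.
#'
#' @param cohort An `emr_cohort`.
#' @param config A [feature_config()].
#' @param element_table Thematic element lookup.
#' @return A `feature_vocab` tibble `(category, feature, index)`.
#' @export
build_vocabulary <- function(cohort, config = default_feature_config(),
                             element_table = default_element_table()) {
  occ <- featurize_occurrences(cohort, config, element_table)
  parts <- lapply(FEATURE_CATEGORIES, function(cat) {
    counts <- occ |>
      dplyr::filter(.data$category == cat) |>
      dplyr::count(.data$feature)
    kept <- apply_cutoff(stats::setNames(counts$n, counts$feature),
                         config$cutoff[[cat]])
    tibble(category = rep(cat, length(kept)), feature = kept)
  })
  vocab <- dplyr::bind_rows(parts)
  vocab$index <- seq_len(nrow(vocab))
  structure(vocab, class = c("feature_vocab", class(vocab)))
}

#' Death-anchored monthly feature counts
#'
#' Aggregates each patient's featurized events into 61 thirty-day bins
#' anchored backward from the death date (bin 61 = the 30 days ending at
#' death). Every event contributes +1 to its feature in its bin; months
#' without events are zero vectors.
#'
#' @param cohort An `emr_cohort`.
#' @param vocab A `feature_vocab` from [build_vocabulary()].
#' @param config The [feature_config()] used to build the vocabulary.
#' @param element_table Thematic element lookup.
#' @return Numeric array `[61, n_features, n_patients]` of raw counts, with
#'   patient ids as the third dimnames.
#' @export
monthly_counts <- function(cohort, vocab, config = default_feature_config(),
                           element_table = default_element_table()) {
  occ <- featurize_occurrences(cohort, config, element_table)
  occ <- dplyr::inner_join(
    occ, cohort$consultations[c("consult_id", "patient_id", "date")],
    by = "consult_id")
  occ <- dplyr::inner_join(
    occ, cohort$patients[c("patient_id", "death_date")], by = "patient_id")
  occ$month <- month_index(occ$date, occ$death_date)
  occ <- dplyr::inner_join(occ, vocab, by = c("category", "feature"))

  pids <- cohort$patients$patient_id
  arr <- array(0, dim = c(61L, nrow(vocab), length(pids)),
               dimnames = list(NULL, vocab$feature, pids))
  if (nrow(occ) > 0) {
    agg <- occ |>
      dplyr::count(.data$patient_id, .data$month, .data$index)
    arr[cbind(agg$month, agg$index,
              match(agg$patient_id, pids))] <- agg$n
  }
  attr(arr, "vocab") <- vocab
  arr
}

#' Monthly feature vectors for a single record
#'
#' @param cohort An `emr_cohort`.
#' @param patient_id Patient whose record to bin.
#' @inheritParams monthly_counts
#' @return A `61 x n_features` matrix of raw counts.
#' @export
bin_monthly <- function(cohort, patient_id, vocab,
                        config = default_feature_config(),
                        element_table = default_element_table()) {
  arr <- monthly_counts(filter_patients(cohort, patient_id), vocab,
                        config, element_table)
  arr[, , 1, drop = TRUE]
}

#' Normalize monthly counts per feature category
#'
#' Within each (month, category) block, every value is divided by the block
#' maximum, yielding values in [0, 1] with at least one 1 in each non-empty
#' block; all-zero blocks stay zero. This annuls the effect of the number
#' of consultations in a month. `scope = "history"` instead divides by the
#' per-category maximum over the patient's whole 61-month history.
#'
#' @param counts Array from [monthly_counts()].
#' @param scope `"month"` (default) or `"history"`.
#' @return Array of the same shape with values in [0, 1].
#' @export
normalize_monthly <- function(counts, scope = c("month", "history")) {
  scope <- match.arg(scope)
  vocab <- attr(counts, "vocab")
  stopifnot(!is.null(vocab))
  out <- counts
  np <- dim(counts)[3]
  for (cat in unique(vocab$category)) {
    cols <- vocab$index[vocab$category == cat]
    block <- counts[, cols, , drop = FALSE]
    if (scope == "month") {
      mx <- apply(block, c(1, 3), max)          # 61 x n_patients
      mx[mx == 0] <- 1
      denom <- aperm(array(mx, c(61L, np, length(cols))), c(1, 3, 2))
    } else {
      mx <- apply(block, 3, max)                 # per patient
      mx[mx == 0] <- 1
      denom <- aperm(array(mx, c(np, 61L, length(cols))), c(2, 3, 1))
    }
    out[, cols, ] <- block / denom
  }
  attr(out, "vocab") <- vocab
  out
}

#' Extract sliding-window training samples
#'
#' Slides a window of `window` consecutive months (stride 1) over each
#' patient's 61 normalized monthly vectors. A window ending at month `t`
#' is labelled `61 - t` months to death; only labels 1..50 are kept, so
#' the month containing death is never part of a label and, at the default
#' window of 10, each patient contributes exactly 50 samples whose labels
#' are a bijection onto 1..50.
#'
#' @param normalized Array from [normalize_monthly()].
#' @param window Window length in months (default 10).
#' @return A `window_set`: list with `x`, a
#'   `[n_features, window, n_samples]` array, and `meta`, a tibble
#'   `(patient_id, label, end_month)`.
#' @export
extract_windows <- function(normalized, window = 10L) {
  window <- as.integer(window)
  if (window < 1L || window > 61L) {
    stop("window must be between 1 and the 61-month history length")
  }
  ends <- seq.int(max(window, 11L), 60L)
  labels <- 61L - ends
  pids <- dimnames(normalized)[[3]]
  nf <- dim(normalized)[2]
  n_samples <- length(ends) * length(pids)
  x <- array(0, dim = c(nf, window, n_samples))
  meta <- tibble(
    patient_id = rep(pids, each = length(ends)),
    label = rep(labels, times = length(pids)),
    end_month = rep(ends, times = length(pids))
  )
  s <- 0L
  for (p in seq_along(pids)) {
    mat <- t(normalized[, , p])                  # n_features x 61
    for (i in seq_along(ends)) {
      s <- s + 1L
      x[, , s] <- mat[, (ends[i] - window + 1L):ends[i]]
    }
  }
  structure(list(x = x, meta = meta), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> ", dim(x$x)[3], " samples, ", dim(x$x)[1],
      " features, window ", dim(x$x)[2], "\n", sep = "")
  invisible(x)
}

#' Percent reduction between two feature-set sizes
#'
#' @param from,to Feature counts before and after reduction.
#' @return Percentage reduction, `100 * (1 - to / from)`.
#' @export
percent_reduction <- function(from, to) {
  stopifnot(from > 0, to >= 0)
  100 * (1 - to / from)
}
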
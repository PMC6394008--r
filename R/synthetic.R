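#' Default clinical vocabularies for the synthetic generator
#'
#' Small per-category code lists in ICPC/ICD form `[letter][number].[dec]`,
#' a closed set of consultation types, medication and lab names, and a
#' background word list for free-text documents. These are synthetic
#' stand-ins shaped like the real coding systems, not real code meanings.
#'
#' @return Named list with elements `code_vocab` (per event category),
#'   `consultation_types`, `consultation_type_weights`, `medication_vocab`,
#'   `lab_vocab`, `text_vocab`.
#' @export
default_vocabularies <- function() {
  list(
    code_vocab = list(
      diagnosis_icpc = c("K86.01", "D84.02", "R95.01", "T90.02",
                         "K77.01", "P76.02", "L84.01", "A04.01"),
      reason_for_encounter_icpc = c("A01.01", "D02.01", "K01.02", "L03.01",
                                    "R05.01", "P03.01"),
      icd = c("I10.9", "J44.1", "E11.9", "C34.9", "I50.0", "F03.9"),
      intervention_icpc = c("K40.1", "D45.2", "A44.1", "L54.3"),
      medical_history_icpc = c("K75.01", "D75.02", "N89.01")
    ),
    consultation_types = c("visit", "home_visit", "phone", "administrative"),
    consultation_type_weights = c(0.45, 0.10, 0.25, 0.20),
    medication_vocab = c("paracetamol", "metoprolol", "omeprazol",
                         "simvastatine", "furosemide", "insuline",
                         "morfine", "temazepam"),
    lab_vocab = c("HB", "GLUC", "KREA", "CRP", "NATR", "KAL"),
    text_vocab = c("patient", "heeft", "pijn", "klachten", "controle",
                   "bloeddruk", "medicatie", "gesprek", "onderzoek", "been",
                   "rug", "hoofd", "slokdarm", "maag", "hart", "longen",
                   "gewicht", "moe", "koorts", "hoest", "verwijzing",
                   "uitslag", "stabiel", "goed", "vandaag", "week",
                   "huisarts", "recept", "afspraak", "besproken")
  )
}

#' Specify a plantable prognostic signal
#'
#' The generator can plant two kinds of recoverable signal: a structured
#' marker code emitted in exactly one death-anchored month, and terminal
#' keywords whose per-document emission probability ramps up linearly as
#' death approaches.
#'
#' @param marker_code Clinical code used as the marker; must match the code
#'   pattern and must not occur in the background code vocabulary.
#' @param marker_offset Months before death (1-50) in which the marker is
#'   emitted.
#' @param marker_penetrance Probability that a patient carries the marker.
#' @param terminal_keywords Words whose emission ramps up near death.
#' @param keyword_ramp_start Months before death at which the keyword
#'   emission probability starts rising linearly from 0.
#' @param keyword_ramp_peak Per-document emission probability reached in the
#'   final month of life.
#' @return A `signal_spec` list.
#' @export
signal_spec <- function(marker_code = "Z99",
                        marker_offset = 5L,
                        marker_penetrance = 0,
                        terminal_keywords = c("terminaal", "palliatief"),
                        keyword_ramp_start = 6L,
                        keyword_ramp_peak = 0.6) {
  stopifnot(
    grepl(CODE_PATTERN, marker_code),
    marker_offset >= 1, marker_offset <= 50,
    marker_penetrance >= 0, marker_penetrance <= 1,
    keyword_ramp_start >= 1,
    keyword_ramp_peak >= 0, keyword_ramp_peak <= 1
  )
  structure(
    list(
      marker_code = marker_code,
      marker_offset = as.integer(marker_offset),
      marker_penetrance = marker_penetrance,
      terminal_keywords = terminal_keywords,
      keyword_ramp_start = as.integer(keyword_ramp_start),
      keyword_ramp_peak = keyword_ramp_peak
    ),
    class = "signal_spec"
  )
}

#' Generator configuration
#'
#' All knobs of the synthetic cohort generator. The defaults are calibrated
#' to the descriptive statistics of the study population the package
#' emulates: 52% female, mean age at death 81 (F) / 76 (M), 121
#' consultations per patient over the final five years of life, documents on
#' 75% of consultations with an 85%/15% note/letter split.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param female_fraction Probability that a patient is female.
#' @param death_age_mean_female,death_age_mean_male Mean age at death in
#'   years by sex.
#' @param death_age_sd Standard deviation of age at death (years); the
#'   distribution is normal truncated at 18.
#' @param consultations_per_patient_mean Expected total consultations per
#'   patient over the 61-month history.
#' @param document_probability Probability that a consultation carries a
#'   document.
#' @param note_fraction Probability that a document is a note (vs letter).
#' @param signal A [signal_spec()].
#' @param vocab Vocabularies as from [default_vocabularies()].
#' @param event_rates Named per-consultation Bernoulli rates for the coded
#'   event categories.
#' @param lab_rate,medication_rate Per-consultation rates for lab results
#'   and medication entries.
#' @param words_per_doc_mean Mean number of background words per document.
#' @param hazard_multiplier Optional length-61 positive vector of relative
#'   monthly consultation rates (index 1 = earliest month); rescaled so the
#'   expected total stays `consultations_per_patient_mean`. Default uniform.
#' @param cohort_end_date Latest possible death date; death dates are spread
#'   uniformly over the 3 years before it so a recency split is meaningful.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 100L,
                             seed = 1L,
                             female_fraction = 0.52,
                             death_age_mean_female = 81,
                             death_age_mean_male = 76,
                             death_age_sd = 8,
                             consultations_per_patient_mean = 121,
                             document_probability = 0.75,
                             note_fraction = 0.85,
                             signal = signal_spec(),
                             vocab = default_vocabularies(),
                             event_rates = c(diagnosis_icpc = 0.85,
                                             reason_for_encounter_icpc = 0.75,
                                             icd = 0.15,
                                             intervention_icpc = 0.30,
                                             medical_history_icpc = 0.10),
                             lab_rate = 0.25,
                             medication_rate = 0.45,
                             words_per_doc_mean = 9,
                             hazard_multiplier = NULL,
                             cohort_end_date = as.Date("2019-12-31")) {
  stopifnot(
    n_patients >= 1,
    female_fraction >= 0, female_fraction <= 1,
    document_probability >= 0, document_probability <= 1,
    note_fraction >= 0, note_fraction <= 1,
    consultations_per_patient_mean > 0,
    inherits(signal, "signal_spec")
  )
  if (any(lengths(vocab$code_vocab) == 0) || length(vocab$text_vocab) == 0) {
    stop("generator vocabularies must be non-empty")
  }
  if (!is.null(hazard_multiplier)) {
    stopifnot(length(hazard_multiplier) == 61, all(hazard_multiplier > 0))
  }
  if (signal$marker_code %in% unlist(vocab$code_vocab)) {
    stop("marker_code '", signal$marker_code,
         "' collides with the background code vocabulary")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      female_fraction = female_fraction,
      death_age_mean_female = death_age_mean_female,
      death_age_mean_male = death_age_mean_male,
      death_age_sd = death_age_sd,
      consultations_per_patient_mean = consultations_per_patient_mean,
      document_probability = document_probability,
      note_fraction = note_fraction,
      signal = signal, vocab = vocab, event_rates = event_rates,
      lab_rate = lab_rate, medication_rate = medication_rate,
      words_per_doc_mean = words_per_doc_mean,
      hazard_multiplier = hazard_multiplier,
      cohort_end_date = as.Date(cohort_end_date)
    ),
    class = "generator_config"
  )
}

#' Calibrated default generator configuration
#'
#' @param seed Integer seed.
#' @param n_patients Number of patients (default 100).
#' @return A `generator_config` with the calibrated population defaults.
#' @export
default_config <- function(seed, n_patients = 100L) {
  generator_config(n_patients = n_patients, seed = seed)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  code
}

rtruncnorm_min <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) {
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd)
  }
  x
}

letter_header <- function(n) {
  rep("Geachte collega,", n)
}

letter_footer <- function(n) {
  rep("Met vriendelijke groet, dr. Jansen", n)
}

#' Generate a synthetic EMR cohort
#'
#' Generates `config$n_patients` deceased patients whose records span the 61
#' death-anchored months. Consultation counts are Poisson over the 61
#' monthly rates; each consultation carries coded events, labs, medications
#' and (with `document_probability`) a note or letter whose text is sampled
#' from the background vocabulary. Letters carry greeting/signature
#' boilerplate. If the signal specifies a positive marker penetrance, the
#' marker code is emitted in exactly the month `marker_offset` months before
#' death for the selected patients, and terminal-keyword emission ramps up
#' linearly over the final `keyword_ramp_start` months.
#'
#' The same configuration (including seed) always yields an identical
#' cohort.
#'
#' @param config A [generator_config()].
#' @return An `emr_cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_preserved_rng({
    set.seed(config$seed)
    generate_cohort_impl(config)
  })
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  sg <- config$signal
  vb <- config$vocab

  patient_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  death_date <- config$cohort_end_date -
    sample.int(3L * 365L, n, replace = TRUE) + 1L
  age_mean <- ifelse(sex == "female",
                     config$death_age_mean_female, config$death_age_mean_male)
  age <- rtruncnorm_min(n, age_mean, config$death_age_sd, lower = 18)
  birth_date <- death_date - round(age * 365.25)
  patients <- tibble(patient_id = patient_id, sex = sex,
                     birth_date = birth_date, death_date = death_date)

  hz <- config$hazard_multiplier %||% rep(1, 61)
  lambda <- config$consultations_per_patient_mean * hz / sum(hz)
  counts <- matrix(stats::rpois(n * 61L, rep(lambda, each = n)), nrow = n)

  ncons <- sum(counts)
  pat_idx <- rep(rep(seq_len(n), 61L), as.vector(counts))
  mtd <- rep(rep(1:61, each = n), as.vector(counts))  # months before death
  days_before <- (mtd - 1L) * 30L + sample.int(30L, ncons, replace = TRUE) - 1L

  # guarantee the marker month has a consultation for marked patients
  marked <- which(stats::runif(n) < sg$marker_penetrance)
  if (length(marked) > 0) {
    has_marker_month <- unique(pat_idx[mtd == sg$marker_offset + 1L])
    need <- setdiff(marked, has_marker_month)
    if (length(need) > 0) {
      pat_idx <- c(pat_idx, need)
      mtd <- c(mtd, rep(sg$marker_offset + 1L, length(need)))
      days_before <- c(days_before,
                       rep(sg$marker_offset * 30L + 15L, length(need)))
      ncons <- length(pat_idx)
    }
  }

  cons <- tibble(
    consult_id = seq_len(ncons),
    patient_id = patient_id[pat_idx],
    date = patients$death_date[pat_idx] - days_before,
    consultation_type = sample(vb$consultation_types, ncons, replace = TRUE,
                               prob = vb$consultation_type_weights)
  )

  # coded events: one Bernoulli draw per (consultation, category)
  ev_parts <- purrr::imap(config$event_rates, function(rate, cat) {
    hit <- which(stats::runif(ncons) < rate)
    tibble(
      consult_id = hit,
      category = rep(cat, length(hit)),
      code = sample(vb$code_vocab[[cat]], length(hit), replace = TRUE)
    )
  })
  events <- dplyr::bind_rows(ev_parts)

  # plant the marker in exactly the marker month
  if (length(marked) > 0) {
    marker_cons <- tibble(cid = seq_len(ncons), pat = pat_idx, mtd = mtd) |>
      dplyr::filter(.data$pat %in% marked,
                    .data$mtd == sg$marker_offset + 1L) |>
      dplyr::group_by(.data$pat) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()
    events <- dplyr::bind_rows(events, tibble(
      consult_id = marker_cons$cid,
      category = "diagnosis_icpc",
      code = sg$marker_code
    ))
  }

  hit <- which(stats::runif(ncons) < config$lab_rate)
  labs <- tibble(
    consult_id = hit,
    lab_code = sample(vb$lab_vocab, length(hit), replace = TRUE),
    value = sprintf("%.1f", stats::runif(length(hit), 1, 20)),
    flag = sample(LAB_FLAGS, length(hit), replace = TRUE,
                  prob = c(0.70, 0.15, 0.15))
  )

  hit <- which(stats::runif(ncons) < config$medication_rate)
  dose <- paste0(sample(c(100L, 250L, 500L, 40L, 10L), length(hit),
                        replace = TRUE), "mg ",
                 sample(1:3, length(hit), replace = TRUE), "dd")
  medications <- tibble(
    consult_id = hit,
    medication = paste(sample(vb$medication_vocab, length(hit), replace = TRUE),
                       dose)
  )

  hit <- which(stats::runif(ncons) < config$document_probability)
  ndoc <- length(hit)
  doc_type <- ifelse(stats::runif(ndoc) < config$note_fraction,
                     "note", "letter")
  nwords <- 3L + stats::rpois(ndoc, config$words_per_doc_mean - 3)
  word_pool <- c(vb$text_vocab, "pt", "pat")  # abbreviations appear in raw text
  body <- vapply(nwords, function(k) {
    paste(sample(word_pool, k, replace = TRUE), collapse = " ")
  }, "")
  # terminal-keyword ramp: p(mtd) rises linearly from 0 at ramp_start to
  # the peak in the final month of life
  p_kw <- sg$keyword_ramp_peak *
    pmax(0, 1 - (mtd[hit] - 1L) / sg$keyword_ramp_start)
  for (kw in sg$terminal_keywords) {
    add <- stats::runif(ndoc) < p_kw
    body[add] <- paste(body[add], kw)
  }
  text <- ifelse(doc_type == "letter",
                 paste(letter_header(ndoc), body, letter_footer(ndoc),
                       sep = "\n"),
                 body)
  documents <- tibble(consult_id = hit, doc_type = doc_type, text = text)

  sort_cohort(emr_cohort(patients, cons, events, labs, medications, documents))
}
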
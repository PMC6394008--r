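# Hand-built two-patient cohort used across the suite.
tiny_cohort <- function() {
  patients <- tibble::tibble(
    patient_id = c("P1", "P2"),
    sex = c("female", "male"),
    birth_date = as.Date(c("1940-03-01", "1935-07-15")),
    death_date = as.Date(c("2019-06-30", "2018-11-02"))
  )
  consultations <- tibble::tibble(
    consult_id = 1:3,
    patient_id = c("P1", "P1", "P2"),
    date = as.Date(c("2018-01-10", "2019-05-26", "2018-10-01")),
    consultation_type = c("visit", "phone", "visit")
  )
  events <- tibble::tibble(
    consult_id = c(1L, 2L, 3L),
    category = c("diagnosis_icpc", "icd", "diagnosis_icpc"),
    code = c("D84.02", "I10.9", "K86.01")
  )
  labs <- tibble::tibble(
    consult_id = c(1L, 3L),
    lab_code = c("HB", "CRP"),
    value = c("7.2", "45.0"),
    flag = c("normal", "abnormal")
  )
  medications <- tibble::tibble(
    consult_id = 2L,
    medication = "paracetamol 500mg 3dd"
  )
  documents <- tibble::tibble(
    consult_id = c(1L, 2L),
    doc_type = c("note", "letter"),
    text = c("pt heeft pijn",
             "Geachte collega,\npt heeft esophagus klachten\nMet vriendelijke groet, dr. Jansen")
  )
  emr_cohort(patients, consultations, events, labs, medications, documents)
}

# Cohort whose diagnosis codes deterministically encode the absolute month
# index (one consultation per month, code D<m>), so months-to-death is fully
# predictable from the diagnosis category alone; other categories are noise.
month_coded_cohort <- function(n = 30, seed = 1, with_icd = TRUE) {
  set.seed(seed)
  death <- as.Date("2019-12-31") - sample.int(600, n)
  patients <- tibble::tibble(
    patient_id = sprintf("M%03d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    birth_date = death - round(78 * 365.25),
    death_date = death
  )
  cons <- tidyr::expand_grid(patient_id = patients$patient_id, month = 1:61)
  cons <- dplyr::left_join(cons, patients[c("patient_id", "death_date")],
                           by = "patient_id")
  cons$consult_id <- seq_len(nrow(cons))
  cons$date <- cons$death_date - ((61L - cons$month) * 30L + 10L)
  cons$consultation_type <- "visit"
  events <- tibble::tibble(
    consult_id = cons$consult_id,
    category = "diagnosis_icpc",
    code = sprintf("D%d", cons$month)
  )
  if (with_icd) {
    events <- dplyr::bind_rows(events, tibble::tibble(
      consult_id = cons$consult_id,
      category = "icd",
      code = sprintf("I%d.9", sample(10:15, nrow(cons), replace = TRUE))
    ))
  }
  emr_cohort(patients,
             cons[c("consult_id", "patient_id", "date", "consultation_type")],
             events)
}

# Tokenized-document tibble built directly from word count specs:
# counts = named list word -> total occurrences, spread uniformly.
docs_from_counts <- function(counts, month = 55L) {
  tibble::tibble(
    patient_id = "P1",
    consult_id = 1L,
    doc_type = "note",
    source_month = as.integer(month),
    tokens = list(rep(names(counts), unlist(counts)))
  )
}

no_cutoff_config <- function() {
  feature_config(cutoff = stats::setNames(
    rep("none", length(lifehorizon:::FEATURE_CATEGORIES)),
    lifehorizon:::FEATURE_CATEGORIES))
}

# Independent characterization of the coverage rule: the dropped set is the
# unique maximal set S with mass(S) <= 25% such that every dropped feature
# precedes every kept feature in (count asc, name desc) priority.
coverage_oracle <- function(counts) {
  nm <- names(counts)
  pri <- order(counts, -rank(nm))  # drop priority
  best <- character()
  for (k in seq_along(pri)) {
    s <- pri[seq_len(k)]
    if (sum(counts[s]) <= 0.25 * sum(counts)) best <- nm[s] else break
  }
  sort(setdiff(nm, best))
}

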
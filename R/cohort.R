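#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

CODE_PATTERN <- "^[A-Z][0-9]+(\\.[0-9]+)?$"
EVENT_CATEGORIES <- c(
  "diagnosis_icpc", "reason_for_encounter_icpc", "icd",
  "intervention_icpc", "medical_history_icpc"
)
LAB_FLAGS <- c("normal", "irregular", "abnormal")
#  history window: 61 thirty-day bins
HISTORY_DAYS <- 61L * 30L

empty_patients <- function() {
  tibble(
    patient_id = character(), sex = character(),
    birth_date = as.Date(character()), death_date = as.Date(character())
  )
}

empty_consultations <- function() {
  tibble(
    consult_id = integer(), patient_id = character(),
    date = as.Date(character()), consultation_type = character()
  )
}

#' Construct an EMR cohort
#'
#' An `emr_cohort` is a relational container for the medical histories of
#' deceased patients: one manifest row per patient plus dated consultations
#' carrying coded events, lab results, medications and free-text documents.
#' All component tables are tibbles keyed by `patient_id` and `consult_id`.
#'
#' @param patients Tibble with columns `patient_id`, `sex`
#'   (`"female"`/`"male"`), `birth_date`, `death_date` (`Date`).
#' @param consultations Tibble with `consult_id`, `patient_id`, `date`,
#'   `consultation_type`.
#' @param events Coded clinical events: `consult_id`, `category` (one of
#'   diagnosis_icpc, reason_for_encounter_icpc, icd, intervention_icpc,
#'   medical_history_icpc), `code` (ICPC/ICD form `[letter][number].[dec]`).
#' @param labs Lab results: `consult_id`, `lab_code`, `value`, `flag`
#'   (normal/irregular/abnormal).
#' @param medications Raw medication strings (may carry dosage text):
#'   `consult_id`, `medication`.
#' @param documents Free text: `consult_id`, `doc_type` (`"note"`/`"letter"`),
#'   `text`.
#' @return An object of class `emr_cohort`.
#' @export
emr_cohort <- function(patients = empty_patients(),
                       consultations = empty_consultations(),
                       events = tibble(consult_id = integer(),
                                       category = character(),
                                       code = character()),
                       labs = tibble(consult_id = integer(),
                                     lab_code = character(),
                                     value = character(),
                                     flag = character()),
                       medications = tibble(consult_id = integer(),
                                            medication = character()),
                       documents = tibble(consult_id = integer(),
                                          doc_type = character(),
                                          text = character())) {
  cohort <- structure(
    list(
      patients = as_tibble(patients),
      consultations = as_tibble(consultations),
      events = as_tibble(events),
      labs = as_tibble(labs),
      medications = as_tibble(medications),
      documents = as_tibble(documents)
    ),
    class = "emr_cohort"
  )
  if (anyDuplicated(cohort$patients$patient_id) > 0) {
    dup <- unique(cohort$patients$patient_id[duplicated(cohort$patients$patient_id)])
    stop("duplicate patient_id in cohort: ", paste(dup, collapse = ", "))
  }
  orphans <- setdiff(cohort$consultations$patient_id, cohort$patients$patient_id)
  if (length(orphans) > 0) {
    stop("consultation refers to patient absent from manifest: ",
         paste(orphans, collapse = ", "))
  }
  cohort
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("<emr_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$consultations), " consultations, ",
      nrow(x$documents), " documents\n", sep = "")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An `emr_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

#' Subset a cohort by patient id
#'
#' @param cohort An `emr_cohort`.
#' @param patient_ids Character vector of ids to keep.
#' @return An `emr_cohort` restricted to those patients (consultation ids
#'   are preserved, not renumbered).
#' @export
filter_patients <- function(cohort, patient_ids) {
  keep_cons <- cohort$consultations$patient_id %in% patient_ids
  cids <- cohort$consultations$consult_id[keep_cons]
  emr_cohort(
    patients = cohort$patients[cohort$patients$patient_id %in% patient_ids, ],
    consultations = cohort$consultations[keep_cons, ],
    events = cohort$events[cohort$events$consult_id %in% cids, ],
    labs = cohort$labs[cohort$labs$consult_id %in% cids, ],
    medications = cohort$medications[cohort$medications$consult_id %in% cids, ],
    documents = cohort$documents[cohort$documents$consult_id %in% cids, ]
  )
}

parse_iso_dates <- function(x, what, lines) {
  d <- as.Date(x, format = "%Y-%m-%d")
  # as.Date() accepts "2020-1-1"; insist on strict ISO-8601 for byte-stability
  strict <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  bad <- which(is.na(d) | !strict)
  if (length(bad) > 0) {
    stop(sprintf("malformed date '%s' in %s at line %d",
                 x[bad[1]], what, lines[bad[1]]))
  }
  d
}

#' Read a cohort from the plain-text interchange format
#'
#' The interchange format is a CSV manifest
#' (`patient_id,sex,birth_date,death_date`, ISO-8601 dates) plus a JSON-lines
#' event log with one consultation object per line carrying the keys
#' `patient_id, date, consultation_type, events, labs, medications,
#' documents`.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param events_path Path to the JSON-lines consultation log.
#' @return An `emr_cohort` with consultations sorted by patient id and date.
#' @export
read_cohort <- function(manifest_path, events_path) {
  man <- utils::read.csv(manifest_path, colClasses = "character",
                         check.names = FALSE)
  expected <- c("patient_id", "sex", "birth_date", "death_date")
  if (!identical(names(man), expected)) {
    stop("manifest header must be exactly: ", paste(expected, collapse = ","))
  }
  man <- as_tibble(man)
  lines <- seq_len(nrow(man)) + 1L
  bad_sex <- which(!man$sex %in% c("female", "male"))
  if (length(bad_sex) > 0) {
    stop(sprintf("invalid sex '%s' in manifest at line %d",
                 man$sex[bad_sex[1]], lines[bad_sex[1]]))
  }
  patients <- tibble(
    patient_id = man$patient_id,
    sex = man$sex,
    birth_date = parse_iso_dates(man$birth_date, "manifest", lines),
    death_date = parse_iso_dates(man$death_date, "manifest", lines)
  )

  raw <- readLines(events_path, encoding = "UTF-8")
  raw_n <- seq_along(raw)
  keep <- nzchar(trimws(raw))
  raw <- raw[keep]
  raw_n <- raw_n[keep]
  parsed <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    parsed[[i]] <- tryCatch(
      jsonlite::fromJSON(raw[i], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("malformed JSON in events file at line %d: %s",
                     raw_n[i], conditionMessage(e)))
      }
    )
  }

  pids <- vapply(parsed, function(p) p$patient_id %||% NA_character_, "")
  unknown <- setdiff(pids, patients$patient_id)
  if (length(unknown) > 0) {
    stop("events refer to patient_id absent from manifest: ",
         paste(unknown, collapse = ", "))
  }
  dates <- parse_iso_dates(
    vapply(parsed, function(p) p$date %||% "", ""), "events file", raw_n
  )

  consultations <- tibble(
    consult_id = seq_along(parsed),
    patient_id = pids,
    date = dates,
    consultation_type = vapply(parsed, function(p) p$consultation_type %||% "", "")
  )

  gather <- function(field, cols) {
    rows <- purrr::imap(parsed, function(p, i) {
      items <- p[[field]]
      if (length(items) == 0) return(NULL)
      out <- purrr::map(items, function(it) {
        if (is.character(it)) it <- list(it)
        vapply(seq_along(cols), function(j) {
          as.character(it[[j]] %||% NA_character_)
        }, "")
      })
      m <- do.call(rbind, out)
      colnames(m) <- cols
      cbind(tibble(consult_id = rep(i, nrow(m))), as_tibble(m))
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) {
      out <- tibble(consult_id = integer())
      for (cl in cols) out[[cl]] <- character()
    }
    out
  }

  events <- gather("events", c("category", "code"))
  labs <- gather("labs", c("lab_code", "value", "flag"))
  medications <- gather("medications", "medication")
  documents <- gather("documents", c("doc_type", "text"))

  bad_code <- events$code[!grepl(CODE_PATTERN, events$code)]
  if (length(bad_code) > 0) {
    stop("invalid clinical code(s): ", paste(unique(bad_code), collapse = ", "))
  }
  bad_cat <- setdiff(events$category, EVENT_CATEGORIES)
  if (length(bad_cat) > 0) {
    stop("unknown event category: ", paste(bad_cat, collapse = ", "))
  }
  bad_flag <- setdiff(labs$flag, LAB_FLAGS)
  if (length(bad_flag) > 0) {
    stop("unknown lab flag: ", paste(bad_flag, collapse = ", "))
  }

  sort_cohort(emr_cohort(patients, consultations, events, labs,
                         medications, documents))
}

# Canonical ordering: manifest by patient_id; consultations by
# (patient_id, date, original order); consult_ids renumbered 1..n.
sort_cohort <- function(cohort) {
  cohort$patients <- dplyr::arrange(cohort$patients, .data$patient_id)
  cons <- dplyr::arrange(cohort$consultations, .data$patient_id, .data$date)
  remap <- stats::setNames(seq_len(nrow(cons)), cons$consult_id)
  cons$consult_id <- seq_len(nrow(cons))
  relink <- function(tb) {
    tb$consult_id <- unname(remap[as.character(tb$consult_id)])
    dplyr::arrange(tb, .data$consult_id)
  }
  emr_cohort(cohort$patients, cons, relink(cohort$events),
             relink(cohort$labs), relink(cohort$medications),
             relink(cohort$documents))
}

#' Write a cohort to the plain-text interchange format
#'
#' Output is byte-stable: manifest rows are ordered by `patient_id`,
#' consultations by `(patient_id, date)`, and JSON keys are emitted in the
#' fixed order `patient_id, date, consultation_type, events, labs,
#' medications, documents`, so identical cohorts yield identical files.
#'
#' @param cohort An `emr_cohort`.
#' @param manifest_path,events_path Output paths (UTF-8).
#' @return Invisibly, the cohort (canonically sorted as written).
#' @export
write_cohort <- function(cohort, manifest_path, events_path) {
  cohort <- sort_cohort(cohort)
  man <- cohort$patients
  man$birth_date <- format(man$birth_date, "%Y-%m-%d")
  man$death_date <- format(man$death_date, "%Y-%m-%d")
  utils::write.csv(man, manifest_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")

  ev <- split(cohort$events, factor(cohort$events$consult_id,
                                    levels = cohort$consultations$consult_id))
  lb <- split(cohort$labs, factor(cohort$labs$consult_id,
                                  levels = cohort$consultations$consult_id))
  md <- split(cohort$medications, factor(cohort$medications$consult_id,
                                         levels = cohort$consultations$consult_id))
  dc <- split(cohort$documents, factor(cohort$documents$consult_id,
                                       levels = cohort$consultations$consult_id))
  cons <- cohort$consultations
  lines <- character(nrow(cons))
  for (i in seq_len(nrow(cons))) {
    obj <- list(
      patient_id = cons$patient_id[i],
      date = format(cons$date[i], "%Y-%m-%d"),
      consultation_type = cons$consultation_type[i],
      events = purrr::transpose(as.list(ev[[i]][c("category", "code")])),
      labs = purrr::transpose(as.list(lb[[i]][c("lab_code", "value", "flag")])),
      medications = as.list(md[[i]]$medication),
      documents = purrr::transpose(as.list(dc[[i]][c("doc_type", "text")]))
    )
    lines[i] <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  }
  con <- file(events_path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) {
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(cohort)
}

#' Validate a single patient record
#'
#' Checks the record invariants: death after birth, all consultation dates
#' inside the 61-month window ending at death, consultations in ascending
#' date order, well-formed clinical codes, known lab flags, and non-empty
#' consultation types. Violations are reported as human-readable
#' diagnostics, never as errors.
#'
#' @param cohort An `emr_cohort`.
#' @param patient_id Id of the record to validate.
#' @return Character vector of diagnostics; empty when all invariants hold.
#' @export
validate_record <- function(cohort, patient_id) {
  diag <- validate_cohort(cohort)
  diag$message[diag$patient_id == patient_id]
}

#' Validate every record in a cohort
#'
#' @param cohort An `emr_cohort`.
#' @return A tibble `(patient_id, message)` with one row per violation;
#'   zero rows when the whole cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  out <- list()
  p <- cohort$patients
  bad <- p$death_date <= p$birth_date
  if (any(bad)) {
    out[[length(out) + 1L]] <- tibble(
      patient_id = p$patient_id[bad],
      message = sprintf("death_date %s is not after birth_date %s",
                        p$death_date[bad], p$birth_date[bad])
    )
  }
  cons <- dplyr::left_join(cohort$consultations,
                           p[c("patient_id", "death_date")], by = "patient_id")
  days_before <- as.integer(cons$death_date - cons$date)
  bad <- days_before < 0 | days_before >= HISTORY_DAYS
  if (any(bad)) {
    out[[length(out) + 1L]] <- tibble(
      patient_id = cons$patient_id[bad],
      message = sprintf("consultation on %s lies outside the 61-month history ending at death (%s)",
                        cons$date[bad], cons$death_date[bad])
    )
  }
  unordered <- cons |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$date), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(unordered) > 0) {
    out[[length(out) + 1L]] <- tibble(
      patient_id = unordered$patient_id,
      message = "consultations are not in ascending date order"
    )
  }
  empty_type <- cons$consultation_type == "" | is.na(cons$consultation_type)
  if (any(empty_type)) {
    out[[length(out) + 1L]] <- tibble(
      patient_id = cons$patient_id[empty_type],
      message = sprintf("consultation on %s has an empty consultation_type",
                        cons$date[empty_type])
    )
  }
  ev <- dplyr::left_join(cohort$events,
                         cohort$consultations[c("consult_id", "patient_id")],
                         by = "consult_id")
  bad_code <- !grepl(CODE_PATTERN, ev$code)
  if (any(bad_code)) {
    out[[length(out) + 1L]] <- tibble(
      patient_id = ev$patient_id[bad_code],
      message = sprintf("malformed clinical code '%s'", ev$code[bad_code])
    )
  }
  lb <- dplyr::left_join(cohort$labs,
                         cohort$consultations[c("consult_id", "patient_id")],
                         by = "consult_id")
  bad_flag <- !lb$flag %in% LAB_FLAGS
  if (any(bad_flag)) {
    out[[length(out) + 1L]] <- tibble(
      patient_id = lb$patient_id[bad_flag],
      message = sprintf("unknown lab flag '%s'", lb$flag[bad_flag])
    )
  }
  if (length(out) == 0) {
    return(tibble(patient_id = character(), message = character()))
  }
  dplyr::bind_rows(out)
}

#' Descriptive statistics of a cohort
#'
#' Computes the calibration-relevant descriptive statistics: cohort size,
#' female share, mean age at death (overall and by sex), mean consultations
#' per patient over the five-year history, the fraction of consultations
#' carrying at least one document, and the share of notes among documents.
#'
#' @param cohort An `emr_cohort`.
#' @return A one-row tibble of summary statistics.
#' @export
cohort_summary <- function(cohort) {
  p <- cohort$patients
  age <- as.numeric(p$death_date - p$birth_date) / 365.25
  cons_per_patient <- cohort$consultations |>
    dplyr::count(.data$patient_id) |>
    dplyr::right_join(tibble(patient_id = p$patient_id), by = "patient_id") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  with_doc <- unique(cohort$documents$consult_id)
  tibble(
    n_patients = nrow(p),
    female_pct = 100 * mean(p$sex == "female"),
    mean_death_age = mean(age),
    mean_death_age_female = mean(age[p$sex == "female"]),
    mean_death_age_male = mean(age[p$sex == "male"]),
    mean_consultations = mean(cons_per_patient$n),
    document_rate_pct = 100 * mean(cohort$consultations$consult_id %in% with_doc),
    note_share_pct = 100 * mean(cohort$documents$doc_type == "note"),
    n_consultations = nrow(cohort$consultations),
    n_documents = nrow(cohort$documents)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
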
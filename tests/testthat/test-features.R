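test_that("code abstraction produces every documented level", {
  tbl <- tibble::tibble(from = 84L, to = 84L, element = "standard procedure")
  expect_equal(abstract_code("D84.02", "full"), "D84.02")
  expect_equal(abstract_code("D84.02", "letter_number"), "D84")
  expect_equal(abstract_code("D84.02", "letter"), "D")
  expect_equal(abstract_code("D84.02", "element", tbl), "standard procedure")
  expect_equal(abstract_code("D84.02", "letter_element", tbl),
               "D+standard procedure")
  expect_equal(abstract_code(c("K86.01", "I10.9"), "letter_number"),
               c("K86", "I10"))
  expect_error(abstract_code("D84.02", "element",
                             tibble::tibble(from = 1L, to = 10L,
                                            element = "x")), "D84.02")
  expect_error(abstract_code("84D.2", "letter"), "malformed")
})

test_that("medication cleaning strips dosage and usage text", {
  expect_equal(clean_medication("paracetamol 500mg 3dd"), "paracetamol")
  expect_equal(clean_medication("metoprolol"), "metoprolol")
  expect_equal(clean_medication("  insuline  "), "insuline")
  expect_equal(clean_medication("Omeprazol 40 mg"), "omeprazol")
  expect_equal(clean_medication(c("morfine 10mg zn", "temazepam 10mg 1dd")),
               c("morfine", "temazepam"))
})

test_that("only irregular and abnormal lab results are featurized", {
  expect_equal(filter_lab(c("normal", "irregular", "abnormal")),
               c(FALSE, TRUE, TRUE))
})

test_that("the four cut-off rules follow their documented boundaries", {
  expect_equal(apply_cutoff(c(a = 150, b = 99), "absolute_100"), "a")
  expect_equal(apply_cutoff(c(a = 99, b = 1), "relative_1pct"), c("a", "b"))
  expect_equal(apply_cutoff(c(a = 99.9, b = 0.1), "relative_1pct"), "a")
  expect_equal(apply_cutoff(c(a = 70, b = 20, c = 6, d = 4),
                            "bottom_25pct_coverage"), c("a", "b"))
  expect_equal(apply_cutoff(c(a = 1, b = 2), "none"), c("a", "b"))
  expect_equal(apply_cutoff(stats::setNames(numeric(), character()),
                            "absolute_100"), character())
})

test_that("coverage cut-off agrees with enumeration on small random instances", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(1:10, 1)
    counts <- stats::setNames(sample(0:40, n, replace = TRUE),
                              sample(letters, n))
    expect_equal(apply_cutoff(counts, "bottom_25pct_coverage"),
                 coverage_oracle(counts), info = paste("rep", rep))
  }
})

test_that("vocabulary construction abstracts, counts, then cuts off", {
  n_ev <- 150
  cons <- tibble::tibble(
    consult_id = seq_len(n_ev),
    patient_id = "P1",
    date = as.Date("2019-06-01") - (seq_len(n_ev) %% 200),
    consultation_type = "visit"
  )
  pats <- tibble::tibble(patient_id = "P1", sex = "female",
                         birth_date = as.Date("1940-01-01"),
                         death_date = as.Date("2019-06-30"))
  ev <- tibble::tibble(consult_id = seq_len(n_ev),
                       category = "diagnosis_icpc", code = "D84.02")
  co <- emr_cohort(pats, cons, ev)
  v <- build_vocabulary(co)
  expect_true(any(v$category == "diagnosis_icpc" & v$feature == "D84"))

  ev99 <- ev[1:99, ]
  co99 <- emr_cohort(pats, cons, ev99)
  v99 <- build_vocabulary(co99)
  expect_false(any(v99$feature == "D84"))

  expect_equal(nrow(build_vocabulary(emr_cohort())), 0)
})

test_that("monthly binning is death-anchored with exactly 61 bins", {
  pats <- tibble::tibble(patient_id = "P1", sex = "male",
                         birth_date = as.Date("1940-01-01"),
                         death_date = as.Date("2019-06-30"))
  cons <- tibble::tibble(consult_id = 1L, patient_id = "P1",
                         date = as.Date("2019-06-30") - 35L,
                         consultation_type = "visit")
  ev <- tibble::tibble(consult_id = 1L, category = "diagnosis_icpc",
                       code = "D84.02")
  co <- emr_cohort(pats, cons, ev)
  v <- build_vocabulary(co, no_cutoff_config())
  m <- bin_monthly(co, "P1", v, no_cutoff_config())
  expect_equal(dim(m), c(61L, nrow(v)))
  # 35 days before death: second-to-last bin
  expect_equal(unname(m[60, "D84"]), 1)
  expect_equal(sum(m[, "D84"]), 1)
  expect_equal(unname(m[60, "visit"]), 1)
  expect_equal(sum(m), 2)
})

test_that("raw counts are conserved across binning", {
  co <- generate_cohort(default_config(seed = 23, n_patients = 10))
  v <- build_vocabulary(co, no_cutoff_config())
  counts <- monthly_counts(co, v, no_cutoff_config())
  expected <- nrow(co$events) + nrow(co$medications) +
    sum(filter_lab(co$labs$flag)) + nrow(co$consultations)
  expect_equal(sum(counts), expected)
  expect_equal(dim(counts)[1], 61L)
  expect_equal(dim(counts)[3], 10L)
})

test_that("normalization divides each month-category block by its maximum", {
  pats <- tibble::tibble(patient_id = "P1", sex = "male",
                         birth_date = as.Date("1940-01-01"),
                         death_date = as.Date("2019-06-30"))
  cons <- tibble::tibble(
    consult_id = 1:6, patient_id = "P1",
    date = as.Date("2019-06-30") - c(5L, 5L, 5L, 5L, 5L, 5L),
    consultation_type = "visit"
  )
  ev <- tibble::tibble(consult_id = 1:6, category = "diagnosis_icpc",
                       code = c("D84.02", "D84.02", "K86.01", "K86.01",
                                "K86.01", "K86.01"))
  co <- emr_cohort(pats, cons, ev)
  v <- build_vocabulary(co, no_cutoff_config())
  norm <- normalize_monthly(monthly_counts(co, v, no_cutoff_config()))
  # diagnosis counts (2, 4) in the death month -> (0.5, 1)
  expect_equal(unname(norm[61, "D84", 1]), 0.5)
  expect_equal(unname(norm[61, "K86", 1]), 1)
  expect_true(all(norm >= 0 & norm <= 1))
  # untouched months stay zero
  expect_equal(sum(norm[1:60, c("D84", "K86"), 1]), 0)
})

test_that("every non-empty month-category block attains 1 after normalization", {
  co <- generate_cohort(default_config(seed = 29, n_patients = 6))
  v <- build_vocabulary(co, no_cutoff_config())
  norm <- normalize_monthly(monthly_counts(co, v, no_cutoff_config()))
  for (cat in unique(v$category)) {
    cols <- v$index[v$category == cat]
    mx <- apply(norm[, cols, , drop = FALSE], c(1, 3), max)
    expect_true(all(mx %in% c(0, 1)), info = cat)
  }
})

test_that("history-scope normalization uses the per-patient category maximum", {
  co <- generate_cohort(default_config(seed = 29, n_patients = 4))
  v <- build_vocabulary(co, no_cutoff_config())
  counts <- monthly_counts(co, v, no_cutoff_config())
  norm <- normalize_monthly(counts, scope = "history")
  expect_true(all(norm >= 0 & norm <= 1))
  cols <- v$index[v$category == "consultation_type"]
  for (p in 1:4) {
    block <- counts[, cols, p]
    expect_equal(max(norm[, cols, p]), if (max(block) > 0) 1 else 0)
  }
})

test_that("window extraction yields a label bijection onto 1..50 per patient", {
  co <- generate_cohort(default_config(seed = 31, n_patients = 3))
  v <- build_vocabulary(co, no_cutoff_config())
  w <- extract_windows(normalize_monthly(monthly_counts(co, v,
                                                        no_cutoff_config())))
  expect_equal(dim(w$x)[2], 10L)
  expect_equal(dim(w$x)[3], 150L)
  for (p in unique(w$meta$patient_id)) {
    expect_equal(sort(w$meta$label[w$meta$patient_id == p]), 1:50)
  }
  # no window ends in the death month (label 0) or before month 11 (label > 50)
  expect_true(all(w$meta$end_month >= 11 & w$meta$end_month <= 60))
  expect_error(extract_windows(normalize_monthly(
    monthly_counts(co, v, no_cutoff_config())), window = 0), "window")
})

test_that("window tensors contain the months they claim to", {
  co <- generate_cohort(default_config(seed = 37, n_patients = 2))
  v <- build_vocabulary(co, no_cutoff_config())
  norm <- normalize_monthly(monthly_counts(co, v, no_cutoff_config()))
  w <- extract_windows(norm)
  i <- which(w$meta$patient_id == dimnames(norm)[[3]][2] &
               w$meta$label == 7)[1]
  endm <- w$meta$end_month[i]
  expect_equal(endm, 54L)
  expect_equal(w$x[, , i], unname(t(norm[(endm - 9):endm, , 2])))
})

test_that("percent reduction matches the closed form", {
  expect_equal(percent_reduction(200, 50), 75)
  expect_equal(percent_reduction(100, 100), 0)
})
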
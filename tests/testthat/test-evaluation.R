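manifest_only_cohort <- function(n, seed = 1) {
  set.seed(seed)
  death <- as.Date("2019-12-31") - sample.int(1000, n, replace = TRUE)
  emr_cohort(tibble::tibble(
    patient_id = sprintf("Q%05d", seq_len(n)),
    sex = "female",
    birth_date = death - 30000L,
    death_date = death
  ))
}

test_that("recency split holds out the most recent deaths as a clean partition", {
  co <- manifest_only_cohort(10)
  parts <- split_recent(co, 0.1)
  expect_equal(n_patients(parts$test), 1)
  expect_equal(parts$test$patients$death_date, max(co$patients$death_date))
  expect_equal(sort(c(parts$dev$patients$patient_id,
                      parts$test$patients$patient_id)),
               sort(co$patients$patient_id))
  expect_length(intersect(parts$dev$patients$patient_id,
                          parts$test$patients$patient_id), 0)
  expect_true(max(parts$dev$patients$death_date) <=
                min(parts$test$patients$death_date))

  big <- manifest_only_cohort(1270)
  expect_equal(n_patients(split_recent(big, 0.10)$test), 127)
  expect_error(split_recent(co, 0), "test_fraction")
  expect_error(split_recent(co, 1), "test_fraction")
})

test_that("k-fold partitions are disjoint, exhaustive, balanced and seeded", {
  co <- manifest_only_cohort(20)
  folds <- kfold(co, k = 10, seed = 4)
  expect_length(folds, 10)
  vals <- lapply(folds, `[[`, "validation")
  expect_true(all(lengths(vals) == 2))
  expect_equal(sort(unlist(vals)), sort(co$patients$patient_id))
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0)
    expect_equal(sort(c(f$train, f$validation)),
                 sort(co$patients$patient_id))
  }
  expect_identical(kfold(co, 10, seed = 4), folds)
  expect_false(identical(kfold(co, 10, seed = 5), folds))
  expect_error(kfold(co, k = 21, seed = 1), "exceeds")

  co23 <- manifest_only_cohort(23)
  sizes <- lengths(lapply(kfold(co23, 10, 1), `[[`, "validation"))
  expect_lte(diff(range(sizes)), 1)
})

test_that("quotient classification follows the inclusive 0.67/1.33 rule", {
  expect_equal(quotient_class(12, 12)$klass, "accurate")
  expect_equal(quotient_class(12, 12)$quotient, 1)
  expect_equal(quotient_class(10, 20)$klass, "optimistic")
  expect_equal(quotient_class(20, 10)$klass, "pessimistic")
  expect_equal(quotient_class(67, 100)$klass, "accurate")   # boundary
  expect_equal(quotient_class(133, 100)$klass, "accurate")  # boundary
  expect_error(quotient_class(0, 5), "positive")
})

test_that("quotient classifier agrees with brute-force enumeration over 1..50 squared", {
  grid <- expand.grid(actual = 1:50, predicted = 1:50)
  got <- quotient_class(grid$actual, grid$predicted)$klass
  oracle <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    q <- grid$actual[i] / grid$predicted[i]
    oracle[i] <- if (q < 0.67) "optimistic"
    else if (q > 1.33) "pessimistic"
    else "accurate"
  }
  expect_equal(got, oracle)
  expect_equal(chance_accuracy(), mean(oracle == "accurate"))
})

test_that("deviation statistics have the documented sign convention", {
  perfect <- tibble::tibble(actual = 1:5, predicted = 1:5)
  expect_equal(deviation_stats(perfect), tibble::tibble(rmse = 0,
                                                        mean_deviation = 0))
  over3 <- tibble::tibble(actual = c(10, 20), predicted = c(13, 23))
  expect_equal(deviation_stats(over3)$rmse, 3)
  expect_equal(deviation_stats(over3)$mean_deviation, 3)  # + = overestimate
  mixed <- tibble::tibble(actual = c(10, 10), predicted = c(14, 6))
  expect_equal(deviation_stats(mixed)$rmse, 4)
  expect_equal(deviation_stats(mixed)$mean_deviation, 0)
  expect_error(deviation_stats(perfect[0, ]), "no outcomes")
})

test_that("accuracy breakdown percentages sum to 100", {
  all_acc <- tibble::tibble(klass = rep("accurate", 4))
  expect_equal(accuracy_breakdown(all_acc),
               tibble::tibble(accurate_pct = 100, pessimistic_pct = 0,
                              optimistic_pct = 0))
  one_each <- tibble::tibble(klass = c("accurate", "optimistic",
                                       "pessimistic"))
  bd <- accuracy_breakdown(one_each)
  expect_equal(unlist(bd), c(accurate_pct = 100 / 3, pessimistic_pct = 100 / 3,
                             optimistic_pct = 100 / 3))
  expect_equal(sum(bd), 100)
})

test_that("certainty correlations match the definition-level computation", {
  out <- tibble::tibble(
    actual = c(3, 9, 14, 27, 41),
    predicted = c(5, 7, 20, 25, 33),
    certainty = c(0.30, 0.22, 0.15, 0.12, 0.08)
  )
  res <- certainty_analyses(out)
  expect_equal(res$name,
               c("actual_vs_predicted", "certainty_vs_actual",
                 "certainty_vs_predicted", "certainty_vs_abs_error"))
  # definition-level Pearson r for the first row
  x <- out$actual; y <- out$predicted
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r[1], r_def)
  expect_true(all(res$p >= 0 & res$p <= 1))

  # linear maps give exact +-1 correlations; abs error stays non-constant
  self <- tibble::tibble(actual = 1:6, predicted = 2L * (1:6) - 1L,
                         certainty = 0.3 - 0.04 * (1:6))
  rs <- certainty_analyses(self)
  expect_equal(rs$r[1], 1)
  expect_equal(rs$r[2], -1)

  const <- tibble::tibble(actual = 1:5, predicted = rep(3, 5),
                          certainty = runif(5))
  expect_error(certainty_analyses(const), "constant")
  expect_error(certainty_analyses(self[1:2, ]), "at least 3")
})

test_that("prediction histograms count every outcome once", {
  out <- tibble::tibble(actual = c(1, 1, 2, 50), predicted = c(1, 3, 3, 49))
  h <- prediction_histogram(out)
  expect_equal(nrow(h), 50)
  expect_equal(sum(h$actual_n), 4)
  expect_equal(sum(h$predicted_n), 4)
  expect_equal(h$actual_n[1], 2)
  expect_equal(h$predicted_n[3], 2)
  empty <- prediction_histogram(out[0, ])
  expect_true(all(empty$actual_n == 0))
})

test_that("metrics report bundles the analyses coherently", {
  set.seed(10)
  out <- tibble::tibble(
    patient_id = "X",
    actual = rep(1:50, 3),
    predicted = pmin(50, pmax(1, rep(1:50, 3) +
                                sample(-8:8, 150, replace = TRUE))),
    certainty = runif(150, 0.02, 0.4)
  )
  out <- dplyr::bind_cols(out[c("patient_id", "certainty")],
                          quotient_class(out$actual, out$predicted))
  rep <- evaluate_outcomes(out)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$n, 150)
  expect_equal(sum(rep$breakdown), 100)
  expect_equal(sum(rep$histogram$actual_n), 150)
  gl <- glance(rep)
  expect_equal(gl$n, 150)
  expect_equal(tidy(rep), rep$histogram)

  path <- tempfile(fileext = ".json")
  write_metrics_report(rep, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$n, 150)
  expect_equal(parsed$human_reference$accurate_pct, 20)
})
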
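#' Recency-based train/test split
#'
#' Sets apart the most recently deceased patients as the test set,
#' mimicking deployment on new patients. Deterministic: patients are
#' ordered by death date (ties broken by patient id) and the latest
#' `ceiling(test_fraction * N)` form the test cohort.
#'
#' @param cohort An `emr_cohort`.
#' @param test_fraction Fraction held out (default 0.10), in (0, 1).
#' @return List with `dev` and `test` cohorts partitioning the input.
#' @export
split_recent <- function(cohort, test_fraction = 0.10) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  p <- dplyr::arrange(cohort$patients, .data$death_date, .data$patient_id)
  n_test <- ceiling(test_fraction * nrow(p))
  test_ids <- utils::tail(p$patient_id, n_test)
  list(
    dev = filter_patients(cohort, setdiff(p$patient_id, test_ids)),
    test = filter_patients(cohort, test_ids)
  )
}

#' k-fold cross-validation partitions
#'
#' Randomly (seeded) splits the development patients into k disjoint
#' validation folds whose sizes differ by at most one; each fold's
#' training set is the complement.
#'
#' @param cohort An `emr_cohort` (the development set).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return List of k lists, each with character vectors `train` and
#'   `validation`.
#' @export
kfold <- function(cohort, k = 10L, seed = 1L) {
  ids <- cohort$patients$patient_id
  if (k > length(ids)) {
    stop("k = ", k, " exceeds the number of patients (", length(ids), ")")
  }
  shuffled <- with_preserved_rng({
    set.seed(seed)
    sample(ids)
  })
  fold <- rep(seq_len(k), length.out = length(ids))
  lapply(seq_len(k), function(f) {
    list(train = sort(shuffled[fold != f]),
         validation = sort(shuffled[fold == f]))
  })
}

#' Quotient-based prognosis classification
#'
#' The prognostic quotient is `Q = actual / predicted`. A prognosis is
#' accurate when Q lies in [0.67, 1.33] (boundaries inclusive — a 33%
#' proportional margin); Q below 0.67 means the prediction overshot the
#' actual life expectancy (overly optimistic), Q above 1.33 undershot it
#' (overly pessimistic).
#'
#' @param actual,predicted Positive months-to-death vectors.
#' @param bounds Length-2 numeric, the accurate interval (default
#'   `c(0.67, 1.33)`, inclusive).
#' @return Tibble `(actual, predicted, quotient, klass)`.
#' @export
quotient_class <- function(actual, predicted, bounds = c(0.67, 1.33)) {
  if (any(actual <= 0) || any(predicted <= 0)) {
    stop("actual and predicted life expectancy must be positive")
  }
  q <- actual / predicted
  klass <- dplyr::case_when(
    q < bounds[1] ~ "optimistic",
    q > bounds[2] ~ "pessimistic",
    .default = "accurate"
  )
  tibble(actual = actual, predicted = predicted, quotient = q, klass = klass)
}

#' Assemble prognosis outcomes from model predictions
#'
#' @param predictions Tibble from [predict.lstm_model()] with columns
#'   `patient_id`, `actual`, `predicted`, `certainty`.
#' @return Tibble of outcomes with quotient and class columns appended.
#' @export
prognosis_outcomes <- function(predictions) {
  qc <- quotient_class(predictions$actual, predictions$predicted)
  dplyr::bind_cols(predictions[c("patient_id", "certainty")],
                   qc)[, c("patient_id", "actual", "predicted",
                           "quotient", "klass", "certainty")]
}

#' Deviation statistics between predicted and actual life expectancy
#'
#' Root-mean-square error and signed mean deviation, both in months. The
#' deviation is `predicted - actual`, so a positive mean means the model
#' overestimates life expectancy and a negative mean means it
#' underestimates.
#'
#' @param outcomes Outcome tibble with `actual` and `predicted`.
#' @return Tibble `(rmse, mean_deviation)`.
#' @export
deviation_stats <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("no outcomes")
  d <- outcomes$predicted - outcomes$actual
  tibble(rmse = sqrt(mean(d^2)), mean_deviation = mean(d))
}

#' Accuracy / optimistic / pessimistic breakdown
#'
#' @param outcomes Outcome tibble with a `klass` column.
#' @return Tibble `(accurate_pct, pessimistic_pct, optimistic_pct)`,
#'   summing to 100 up to rounding.
#' @export
accuracy_breakdown <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("no outcomes")
  tibble(
    accurate_pct = 100 * mean(outcomes$klass == "accurate"),
    pessimistic_pct = 100 * mean(outcomes$klass == "pessimistic"),
    optimistic_pct = 100 * mean(outcomes$klass == "optimistic")
  )
}

#' Correlation analyses of prediction certainty
#'
#' Pearson product-moment correlations (with two-sided p-values) between:
#' actual and predicted life expectancy; certainty and actual; certainty
#' and predicted; and certainty and the absolute actual-predicted
#' difference.
#'
#' @param outcomes Outcome tibble with `actual`, `predicted`, `certainty`.
#' @return Tibble `(name, r, p)` with four rows.
#' @export
certainty_analyses <- function(outcomes) {
  if (nrow(outcomes) < 3) stop("need at least 3 outcomes")
  pairs <- list(
    "actual_vs_predicted" = list(outcomes$actual, outcomes$predicted),
    "certainty_vs_actual" = list(outcomes$certainty, outcomes$actual),
    "certainty_vs_predicted" = list(outcomes$certainty, outcomes$predicted),
    "certainty_vs_abs_error" = list(outcomes$certainty,
                                    abs(outcomes$actual - outcomes$predicted))
  )
  purrr::imap(pairs, function(xy, nm) {
    if (stats::sd(xy[[1]]) == 0 || stats::sd(xy[[2]]) == 0) {
      stop("correlation undefined for constant series: ", nm)
    }
    ct <- stats::cor.test(xy[[1]], xy[[2]], method = "pearson")
    tibble(name = nm, r = unname(ct$estimate), p = ct$p.value)
  }) |>
    dplyr::bind_rows()
}

#' Frequency histogram of actual and predicted life expectancies
#'
#' @param outcomes Outcome tibble.
#' @param horizon Month range (default 50).
#' @return Tibble `(month, actual_n, predicted_n)` over 1..horizon; both
#'   count columns sum to the number of outcomes.
#' @export
prediction_histogram <- function(outcomes, horizon = 50L) {
  tibble(
    month = seq_len(horizon),
    actual_n = as.integer(table(factor(outcomes$actual,
                                       levels = seq_len(horizon)))),
    predicted_n = as.integer(table(factor(outcomes$predicted,
                                          levels = seq_len(horizon))))
  )
}

#' Chance-level quotient accuracy by enumeration
#'
#' The quotient accuracy a uniform-random predictor attains against
#' uniform labels, computed by brute-force enumeration of all
#' (actual, predicted) pairs in `{1..horizon}^2`.
#'
#' @param horizon Month range (default 50).
#' @param bounds Accurate-quotient interval.
#' @return Fraction of pairs classified accurate.
#' @export
chance_accuracy <- function(horizon = 50L, bounds = c(0.67, 1.33)) {
  grid <- expand.grid(actual = seq_len(horizon), predicted = seq_len(horizon))
  q <- grid$actual / grid$predicted
  mean(q >= bounds[1] & q <= bounds[2])
}

#' Full metrics report for a set of prognosis outcomes
#'
#' Bundles deviation statistics, the accuracy taxonomy, the prediction
#' histogram, and (when the series are non-constant) the certainty
#' correlation analyses. The hospice-study human reference constants
#' (20% accurate / 17% pessimistic / 63% optimistic) are carried alongside
#' for context.
#'
#' @param outcomes Outcome tibble from [prognosis_outcomes()].
#' @return A `metrics_report`.
#' @export
evaluate_outcomes <- function(outcomes) {
  correlations <- tryCatch(certainty_analyses(outcomes),
                           error = function(e) NULL)
  structure(
    list(
      n = nrow(outcomes),
      deviation = deviation_stats(outcomes),
      breakdown = accuracy_breakdown(outcomes),
      histogram = prediction_histogram(outcomes),
      correlations = correlations,
      human_reference = tibble(accurate_pct = 20, pessimistic_pct = 17,
                               optimistic_pct = 63),
      outcomes = outcomes
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Prognostic evaluation over", x$n, "window samples\n")
  cat(sprintf("  RMSE %.1f months, mean deviation %+.1f months\n",
              x$deviation$rmse, x$deviation$mean_deviation))
  cat(sprintf("  accurate %.0f%% | pessimistic %.0f%% | optimistic %.0f%%\n",
              x$breakdown$accurate_pct, x$breakdown$pessimistic_pct,
              x$breakdown$optimistic_pct))
  cat("  (human hospice reference: 20% | 17% | 63%)\n")
  if (!is.null(x$correlations)) {
    for (i in seq_len(nrow(x$correlations))) {
      cat(sprintf("  %s: r = %+.2f (p = %.3g)\n", x$correlations$name[i],
                  x$correlations$r[i], x$correlations$p[i]))
    }
  }
  invisible(x)
}

#' Per-month histogram rows of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The `(month, actual_n, predicted_n)` tibble.
#' @export
tidy.metrics_report <- function(x, ...) x$histogram

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble with n, RMSE, mean deviation and the class
#'   percentages.
#' @export
glance.metrics_report <- function(x, ...) {
  dplyr::bind_cols(tibble(n = x$n), x$deviation, x$breakdown)
}

#' Serialize a metrics report to JSON
#'
#' Key order and number formatting are fixed, so identical reports yield
#' byte-identical files.
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_report <- function(report, path) {
  obj <- list(
    n = report$n,
    deviation = as.list(report$deviation),
    breakdown = as.list(report$breakdown),
    correlations = if (is.null(report$correlations)) NULL else
      lapply(seq_len(nrow(report$correlations)), function(i)
        as.list(report$correlations[i, ])),
    histogram = list(month = report$histogram$month,
                     actual_n = report$histogram$actual_n,
                     predicted_n = report$histogram$predicted_n),
    human_reference = as.list(report$human_reference)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = 12, null = "null")),
             con, useBytes = TRUE)
  invisible(path)
}
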
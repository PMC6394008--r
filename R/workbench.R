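#' Derive a stage seed from a master seed
#'
#' One master seed fans out deterministically to per-stage seeds (a stable
#' hash of the stage name mixed with the master), so any stage can be
#' rerun in isolation with the same randomness.
#'
#' @param master Integer master seed.
#' @param stage Stage name.
#' @return Integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483646 + 1)
}

#' Experiment configuration
#'
#' Bundles every stage's configuration for an end-to-end run. The master
#' `seed` fans out to the generator, model and split seeds via
#' [derive_seed()] unless a stage carries its own.
#'
#' @param generator A [generator_config()] (its seed is re-derived from
#'   the master seed).
#' @param features A [feature_config()].
#' @param keywords `NULL` for the baseline (structured features only), or
#'   a list with `method` (`"frequency"`, `"entropy"`, `"embedding"`),
#'   `n` (keyword count, for frequency/entropy), and optionally
#'   `embedding` (an [embedding_config()]).
#' @param model A [model_config()].
#' @param test_fraction Recency-split fraction.
#' @param k Cross-validation folds.
#' @param seed Master seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(generator = default_config(seed = 1L),
                              features = default_feature_config(),
                              keywords = NULL,
                              model = model_config(),
                              test_fraction = 0.10,
                              k = 10L,
                              seed = 1L) {
  if (!is.null(keywords)) {
    stopifnot(keywords$method %in% c("frequency", "entropy", "embedding"))
    if (keywords$method != "embedding" && is.null(keywords$n)) {
      stop("keywords$n is required for frequency/entropy selection")
    }
    if (keywords$method == "embedding" && is.null(keywords$embedding)) {
      keywords$embedding <- embedding_config()
    }
  }
  structure(
    list(generator = generator, features = features, keywords = keywords,
         model = model, test_fraction = test_fraction, k = as.integer(k),
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

build_text_features <- function(docs, keywords, patient_ids, master_seed) {
  if (keywords$method == "embedding") {
    model <- train_embeddings(docs, keywords$embedding,
                              seed = derive_seed(master_seed, "embedding"))
    list(type = "embedding",
         features = embedding_month_features(docs, model, patient_ids),
         model = model)
  } else {
    kws <- select_keywords(docs, keywords$method, keywords$n)
    list(type = "keyword",
         features = keyword_month_features(docs, kws, patient_ids),
         keywords = kws)
  }
}

prepare_inputs <- function(cohort, config, vocab, text_selector = NULL) {
  counts <- monthly_counts(cohort, vocab, config$features)
  norm <- normalize_monthly(counts)
  if (!is.null(text_selector)) {
    docs <- preprocess_cohort(cohort)
    tf <- if (text_selector$type == "embedding") {
      embedding_month_features(docs, text_selector$model,
                               cohort$patients$patient_id)
    } else {
      keyword_month_features(docs, text_selector$keywords,
                             cohort$patients$patient_id)
    }
    norm <- assemble_features(norm, tf,
                              text_type = if (text_selector$type == "embedding")
                                "embedding" else "keyword")
  }
  extract_windows(norm, window = config$model$window)
}

#' Run a full experiment
#'
#' Executes the complete pipeline: generate the cohort, hold out the most
#' recent patients, build the feature vocabulary (and, if configured,
#' keyword or embedding text features) on the development set, train the
#' LSTM on all development windows, and evaluate on the held-out windows.
#' Fully reproducible: the same configuration always yields a
#' byte-identical written report.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, `report.json` and
#'   `vocabulary.tsv` are written there.
#' @return A `metrics_report` (invisible extra elements: the trained
#'   model and vocabulary are attached as attributes).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  gen <- config$generator
  gen$seed <- derive_seed(config$seed, "generate")
  cohort <- generate_cohort(gen)

  parts <- split_recent(cohort, config$test_fraction)
  vocab <- build_vocabulary(parts$dev, config$features)

  selector <- NULL
  if (!is.null(config$keywords)) {
    dev_docs <- preprocess_cohort(parts$dev)
    selector <- build_text_features(dev_docs, config$keywords,
                                    parts$dev$patients$patient_id,
                                    config$seed)
  }

  dev_windows <- prepare_inputs(parts$dev, config, vocab, selector)
  test_windows <- prepare_inputs(parts$test, config, vocab, selector)

  mcfg <- config$model
  mcfg$seed <- derive_seed(config$seed, "model")
  model <- build_model(mcfg, input_dim = dim(dev_windows$x)[1])
  model <- train_model(model, dev_windows)

  outcomes <- prognosis_outcomes(predict(model, test_windows))
  report <- evaluate_outcomes(outcomes)
  attr(report, "model") <- model
  attr(report, "vocab") <- vocab

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_report(report, file.path(out_dir, "report.json"))
    utils::write.table(vocab, file.path(out_dir, "vocabulary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report
}

# Cross-validated quotient accuracy (and RMSE) of a model configuration on
# a development cohort, optionally restricted to a subset of feature
# categories.
cv_score <- function(dev, features, mcfg, k, seed, categories = NULL) {
  folds <- kfold(dev, k = k, seed = derive_seed(seed, "folds"))
  per_fold <- purrr::map(folds, function(fd) {
    train_cohort <- filter_patients(dev, fd$train)
    val_cohort <- filter_patients(dev, fd$validation)
    vocab <- build_vocabulary(train_cohort, features)
    if (!is.null(categories)) {
      vocab <- vocab[vocab$category %in% categories, ]
      vocab$index <- seq_len(nrow(vocab))
      class(vocab) <- c("feature_vocab", "tbl_df", "tbl", "data.frame")
    }
    if (nrow(vocab) == 0) {
      return(tibble(accuracy = NA_real_, rmse = NA_real_))
    }
    tr <- extract_windows(normalize_monthly(
      monthly_counts(train_cohort, vocab, features)), mcfg$window)
    va <- extract_windows(normalize_monthly(
      monthly_counts(val_cohort, vocab, features)), mcfg$window)
    m <- build_model(mcfg, input_dim = nrow(vocab)) |> train_model(tr)
    out <- prognosis_outcomes(predict(m, va))
    dplyr::bind_cols(accuracy_breakdown(out)["accurate_pct"] / 100,
                     deviation_stats(out)["rmse"]) |>
      dplyr::rename(accuracy = "accurate_pct")
  })
  dplyr::bind_rows(per_fold) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     rmse = mean(.data$rmse))
}

#' Greedy forward selection of feature categories
#'
#' Adds feature categories one at a time, each round adding the category
#' whose inclusion most improves cross-validated quotient accuracy, and
#' stops when no remaining category improves it. Returns the addition
#' order with per-round scores.
#'
#' @param dev Development `emr_cohort`.
#' @param features A [feature_config()].
#' @param model A [model_config()].
#' @param k Cross-validation folds.
#' @param seed Master seed.
#' @param categories Candidate categories (default all eight).
#' @param score_fn Optional scoring override,
#'   `function(categories) -> accuracy`; the default trains and
#'   cross-validates the LSTM restricted to those categories.
#' @return Tibble `(round, category, accuracy)` in addition order.
#' @export
stepwise_category_selection <- function(dev,
                                        features = default_feature_config(),
                                        model = model_config(),
                                        k = 10L, seed = 1L,
                                        categories = FEATURE_CATEGORIES,
                                        score_fn = NULL) {
  if (length(categories) < 2) stop("need at least 2 candidate categories")
  if (is.null(score_fn)) {
    score_fn <- function(cats) {
      cv_score(dev, features, model, k, seed, categories = cats)$accuracy
    }
  }
  selected <- character()
  best_so_far <- -Inf
  rounds <- list()
  remaining <- categories
  while (length(remaining) > 0) {
    scores <- vapply(remaining, function(cat) {
      s <- score_fn(c(selected, cat))
      if (is.na(s)) -Inf else s
    }, 0)
    cand <- which.max(scores)
    if (scores[cand] <= best_so_far) break
    best_so_far <- scores[cand]
    selected <- c(selected, remaining[cand])
    rounds[[length(rounds) + 1L]] <- tibble(
      round = length(rounds) + 1L,
      category = remaining[cand],
      accuracy = scores[cand]
    )
    remaining <- remaining[-cand]
  }
  dplyr::bind_rows(rounds)
}

#' Grid search over model configurations
#'
#' Scores each configuration by k-fold cross-validated quotient accuracy;
#' the best configuration has the highest accuracy, with lower RMSE used
#' only as a tie breaker.
#'
#' @param configs List of [model_config()]s.
#' @param dev Development `emr_cohort`.
#' @param features A [feature_config()].
#' @param k Folds.
#' @param seed Master seed.
#' @param score_fn Optional override, `function(model_config) -> tibble
#'   (accuracy, rmse)`.
#' @return List with `best` (a `model_config`) and `scores` (one tibble
#'   row per configuration).
#' @export
grid_search <- function(configs, dev, features = default_feature_config(),
                        k = 10L, seed = 1L, score_fn = NULL) {
  stopifnot(length(configs) >= 1)
  if (is.null(score_fn)) {
    score_fn <- function(mcfg) cv_score(dev, features, mcfg, k, seed)
  }
  scores <- purrr::imap(configs, function(mcfg, i) {
    dplyr::bind_cols(tibble(config_id = i,
                            hidden_units = mcfg$hidden_units,
                            window = mcfg$window,
                            learning_rate = mcfg$learning_rate,
                            epochs = mcfg$epochs),
                     score_fn(mcfg))
  }) |>
    dplyr::bind_rows()
  ranked <- dplyr::arrange(scores, dplyr::desc(.data$accuracy), .data$rmse)
  list(best = configs[[ranked$config_id[1]]], scores = scores)
}
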
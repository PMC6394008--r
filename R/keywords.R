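#' Default stop-word list
#'
#' Small Dutch/English function-word list excluded from keyword ranking.
#'
#' @return Character vector.
#' @export
default_stopwords <- function() {
  c("de", "het", "een", "en", "van", "in", "is", "op", "te", "met", "voor",
    "niet", "dat", "die", "ik", "je", "zijn", "the", "a", "of", "and", "to")
}

corpus_counts <- function(docs) {
  words <- unlist(docs$tokens, use.names = FALSE)
  if (length(words) == 0) {
    return(stats::setNames(integer(), character()))
  }
  tb <- table(words)
  stats::setNames(as.integer(tb), names(tb))
}

#' Rank content words by corpus frequency
#'
#' @param docs Tokenized document tibble (as from [preprocess_cohort()]).
#' @param n Number of words to return; if larger than the vocabulary the
#'   full ranked vocabulary is returned.
#' @param stopwords Words excluded from ranking.
#' @return Character vector of up to `n` words, ordered by descending
#'   frequency with lexicographic tie-breaking.
#' @export
rank_by_frequency <- function(docs, n, stopwords = default_stopwords()) {
  stopifnot(n >= 0)
  counts <- corpus_counts(docs)
  counts <- counts[!names(counts) %in% stopwords]
  if (length(counts) == 0 || n == 0) return(character())
  ord <- order(-counts, names(counts))
  utils::head(names(counts)[ord], n)
}

#' Temporal frequency distributions of words over months-to-death
#'
#' Pools all patients' documents by months-to-death (1 = final month of
#' life) and, for each word, builds its frequency distribution over months
#' 1..50 with additive smoothing, so every distribution is strictly
#' positive and sums to 1. Documents more than 50 months before death are
#' outside the label range and are ignored.
#'
#' @param docs Tokenized document tibble with `source_month` (1..61).
#' @param smoothing Pseudo-count added to every month bin (default 1).
#' @return Matrix `words x 50` of probabilities; attribute `"count"` holds
#'   each word's pooled corpus count.
#' @export
temporal_distributions <- function(docs, smoothing = 1) {
  mtd <- 62L - docs$source_month
  keep <- mtd >= 1L & mtd <= 50L
  words <- unlist(docs$tokens[keep], use.names = FALSE)
  reps <- lengths(docs$tokens[keep])
  month <- rep(mtd[keep], reps)
  vocab <- sort(unique(words))
  counts <- matrix(0, nrow = length(vocab), ncol = 50,
                   dimnames = list(vocab, NULL))
  if (length(words) > 0) {
    tb <- table(factor(words, levels = vocab), factor(month, levels = 1:50))
    counts <- counts + as.matrix(unclass(tb))
  }
  total <- rowSums(counts)
  probs <- (counts + smoothing) / (total + 50 * smoothing)
  attr(probs, "count") <- total
  probs
}

#' Kullback-Leibler divergence of a temporal word distribution
#'
#' `sum_m p_m * ln(p_m / q_m)` in nats, with `0 * ln 0 = 0`. A word whose
#' temporal distribution matches the reference scores 0; all scores are
#' non-negative. A reference zero where the distribution is positive is an
#' infinite divergence and raises an error (prevented in practice by
#' smoothing).
#'
#' @param dist Probability vector over months-to-death 1..50.
#' @param reference Reference probability vector of the same length.
#' @return Non-negative KL divergence (nats).
#' @export
kl_score <- function(dist, reference) {
  stopifnot(length(dist) == length(reference),
            abs(sum(dist) - 1) < 1e-6, abs(sum(reference) - 1) < 1e-6)
  pos <- dist > 0
  if (any(pos & reference == 0)) {
    stop("infinite KL divergence: reference is zero where distribution is positive")
  }
  sum(dist[pos] * log(dist[pos] / reference[pos]))
}

#' Reference distributions for entropy-based keyword selection
#'
#' `late_mass_reference()` encodes "relevance grows as death approaches":
#' mass decays exponentially with months-to-death
#' (`ref_m` proportional to `exp(-(m - 1) / tau)`), concentrating the
#' reference in the final months of life. The time constant `tau` sets how
#' sharply; at the default 6 months a word used uniformly through time
#' scores a KL divergence of about 2.0 nats against this reference while a
#' word concentrated in the final months scores well under 1, so terminal
#' vocabulary ranks first. A linear tilt (`ref_m` proportional to `51 - m`)
#' is too mild for that separation — uniform background words then
#' out-score terminal ones — which is why the default is exponential.
#' `uniform_reference()` is the flat alternative.
#'
#' @param horizon Number of months (default 50).
#' @param tau Decay time constant in months (default 6).
#' @return Probability vector of length `horizon`.
#' @export
late_mass_reference <- function(horizon = 50L, tau = 6) {
  w <- exp(-(seq_len(horizon) - 1) / tau)
  w / sum(w)
}

#' @rdname late_mass_reference
#' @export
uniform_reference <- function(horizon = 50L) {
  rep(1 / horizon, horizon)
}

#' Select keyword features
#'
#' `"frequency"` takes the top-`n` most frequent content words.
#' `"entropy"` ranks words ascending by the KL divergence between their
#' pooled temporal distribution over months-to-death and the reference
#' distribution (lowest divergence first), breaking ties by higher
#' frequency then lexicographically. Words whose temporal pattern matches
#' the late-mass reference — e.g. terminal vocabulary concentrated near
#' death — rank at the top.
#'
#' @param docs Tokenized document tibble.
#' @param method `"frequency"` or `"entropy"`.
#' @param n Number of keywords (the study sizes are 100/200/300; any
#'   non-negative n is accepted).
#' @param reference Reference distribution for `"entropy"`.
#' @param stopwords Words excluded from selection.
#' @param smoothing Additive smoothing for the temporal distributions.
#' @return Character vector of up to `n` keywords.
#' @export
select_keywords <- function(docs, method = c("frequency", "entropy"), n,
                            reference = late_mass_reference(),
                            stopwords = default_stopwords(),
                            smoothing = 1) {
  method <- match.arg(method)
  if (n == 0) return(character())
  if (method == "frequency") {
    return(rank_by_frequency(docs, n, stopwords))
  }
  probs <- temporal_distributions(docs, smoothing)
  counts <- attr(probs, "count")
  keep <- !rownames(probs) %in% stopwords
  probs <- probs[keep, , drop = FALSE]
  if (nrow(probs) == 0) return(character())
  counts <- counts[keep]
  lref <- log(reference)
  scores <- rowSums(probs * (log(probs) - matrix(lref, nrow(probs), 50,
                                                 byrow = TRUE)))
  ord <- order(scores, -counts, rownames(probs))
  utils::head(rownames(probs)[ord], n)
}

#' Skip-gram embedding configuration
#'
#' @param dimensions Embedding dimensionality, one of 100/200/300.
#' @param min_count Words with corpus frequency below this are excluded
#'   from the model (default 10).
#' @param context_window Context window size (default 5).
#' @param epochs Training passes over the corpus (default 5).
#' @param negative_samples Negative samples per positive pair (default 5).
#' @param learning_rate Initial SGD learning rate, decayed linearly.
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(dimensions = 300L, min_count = 10L,
                             context_window = 5L, epochs = 5L,
                             negative_samples = 5L, learning_rate = 0.025) {
  stopifnot(dimensions %in% c(100L, 200L, 300L),
            min_count >= 1, context_window >= 1, epochs >= 1,
            negative_samples >= 1, learning_rate > 0)
  structure(
    list(dimensions = as.integer(dimensions),
         min_count = as.integer(min_count),
         context_window = as.integer(context_window),
         epochs = as.integer(epochs),
         negative_samples = as.integer(negative_samples),
         learning_rate = learning_rate),
    class = "embedding_config"
  )
}

#' Train skip-gram word embeddings on a tokenized corpus
#'
#' Single-threaded skip-gram with negative sampling; the tested,
#' deterministic configuration (same corpus and seed give identical
#' vectors).
#'
#' @param docs Tokenized document tibble.
#' @param config An [embedding_config()].
#' @param seed Integer seed.
#' @return A `word_embeddings` matrix (vocabulary x dimensions) with words
#'   as rownames.
#' @export
train_embeddings <- function(docs, config = embedding_config(), seed = 1L) {
  counts <- corpus_counts(docs)
  vocab <- sort(names(counts)[counts >= config$min_count])
  if (length(vocab) == 0) {
    stop("corpus too small: no word reaches min_count = ", config$min_count)
  }
  enc <- lapply(docs$tokens, function(tk) {
    v <- match(tk, vocab)
    as.integer(v[!is.na(v)] - 1L)
  })
  enc <- enc[lengths(enc) > 0]
  w <- counts[vocab]^0.75
  table_size <- 100000L
  unigram <- rep(seq_along(vocab) - 1L,
                 times = pmax(1L, round(table_size * w / sum(w))))
  emb <- sgns_train_cpp(enc, length(vocab), config$dimensions,
                        config$context_window, config$negative_samples,
                        config$epochs, config$learning_rate,
                        as.integer(unigram), as.integer(seed))
  rownames(emb) <- vocab
  structure(emb, class = c("word_embeddings", "matrix", "array"))
}

#' Mean-vector representation of a text
#'
#' The arithmetic mean of the embedding vectors of the in-vocabulary
#' tokens; empty or fully out-of-vocabulary input yields the zero vector.
#' Permutation-invariant in its tokens.
#'
#' @param tokens Character vector of tokens.
#' @param model A `word_embeddings` matrix.
#' @return Numeric vector of the model's dimensionality.
#' @export
embed_month_text <- function(tokens, model) {
  hit <- tokens[tokens %in% rownames(model)]
  if (length(hit) == 0) {
    return(numeric(ncol(model)))
  }
  colMeans(model[hit, , drop = FALSE])
}

#' Monthly keyword-count features
#'
#' Counts each selected keyword's occurrences in the pooled document text
#' of every (patient, month) cell.
#'
#' @param docs Tokenized document tibble.
#' @param keywords Selected keywords (fixes the sub-vector order).
#' @param patient_ids All patients that need feature rows (patients
#'   without documents get zeros).
#' @return Array `[61, length(keywords), n_patients]`.
#' @export
keyword_month_features <- function(docs, keywords, patient_ids) {
  arr <- array(0, dim = c(61L, length(keywords), length(patient_ids)),
               dimnames = list(NULL, keywords, patient_ids))
  if (length(keywords) == 0 || nrow(docs) == 0) return(arr)
  words <- unlist(docs$tokens, use.names = FALSE)
  reps <- lengths(docs$tokens)
  kid <- match(words, keywords)
  keep <- !is.na(kid)
  if (!any(keep)) return(arr)
  month <- rep(docs$source_month, reps)[keep]
  pid <- match(rep(docs$patient_id, reps)[keep], patient_ids)
  agg <- dplyr::count(tibble(month = month, kid = kid[keep], pid = pid),
                      .data$month, .data$kid, .data$pid)
  arr[cbind(agg$month, agg$kid, agg$pid)] <- agg$n
  arr
}

#' Monthly embedding-mean features
#'
#' The mean embedding of all document text in every (patient, month) cell;
#' months without text get the zero vector.
#'
#' @param docs Tokenized document tibble.
#' @param model A `word_embeddings` matrix.
#' @param patient_ids All patients that need feature rows.
#' @return Array `[61, dimensions, n_patients]`.
#' @export
embedding_month_features <- function(docs, model, patient_ids) {
  d <- ncol(model)
  arr <- array(0, dim = c(61L, d, length(patient_ids)),
               dimnames = list(NULL, colnames(model), patient_ids))
  if (nrow(docs) == 0) return(arr)
  cells <- docs |>
    dplyr::group_by(.data$patient_id, .data$source_month) |>
    dplyr::summarise(tokens = list(unlist(.data$tokens, use.names = FALSE)),
                     .groups = "drop")
  for (i in seq_len(nrow(cells))) {
    p <- match(cells$patient_id[i], patient_ids)
    if (is.na(p)) next
    arr[cells$source_month[i], , p] <- embed_month_text(cells$tokens[[i]],
                                                        model)
  }
  arr
}

#' Concatenate text features onto the structured monthly vectors
#'
#' Per month, the text sub-vector is appended after the structured
#' features. Keyword counts are treated as an additional feature category
#' and max-normalized per (month, patient) block; embedding means are
#' passed through unchanged. Structured values are preserved bit-exactly.
#'
#' @param structured Normalized array from [normalize_monthly()].
#' @param text Array from [keyword_month_features()] or
#'   [embedding_month_features()] over the same patients and months.
#' @param text_type `"keyword"` (max-normalize) or `"embedding"`
#'   (pass through).
#' @return Array `[61, n_structured + n_text, n_patients]`.
#' @export
assemble_features <- function(structured, text,
                              text_type = c("keyword", "embedding")) {
  text_type <- match.arg(text_type)
  if (!identical(dim(structured)[c(1, 3)], dim(text)[c(1, 3)]) ||
      !identical(dimnames(structured)[[3]], dimnames(text)[[3]])) {
    stop("structured and text features cover different patients or months")
  }
  if (text_type == "keyword" && dim(text)[2] > 0) {
    mx <- apply(text, c(1, 3), max)
    mx[mx == 0] <- 1
    text <- text / aperm(array(mx, c(61L, dim(text)[3], dim(text)[2])),
                         c(1, 3, 2))
  }
  cn <- c(dimnames(structured)[[2]] %||% rep("", dim(structured)[2]),
          dimnames(text)[[2]] %||% rep("", dim(text)[2]))
  out <- array(0, dim = c(61L, dim(structured)[2] + dim(text)[2],
                          dim(structured)[3]),
               dimnames = list(NULL, cn, dimnames(structured)[[3]]))
  out[, seq_len(dim(structured)[2]), ] <- structured
  if (dim(text)[2] > 0) {
    out[, dim(structured)[2] + seq_len(dim(text)[2]), ] <- text
  }
  out
}
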
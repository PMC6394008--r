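test_that("frequency ranking orders by count with lexicographic ties", {
  docs <- docs_from_counts(list(a = 5, b = 3, c = 1))
  expect_equal(rank_by_frequency(docs, 2, stopwords = character()),
               c("a", "b"))
  tie <- docs_from_counts(list(b = 3, a = 3))
  expect_equal(rank_by_frequency(tie, 1, stopwords = character()), "a")
  expect_equal(rank_by_frequency(docs, 99, stopwords = character()),
               c("a", "b", "c"))
  expect_equal(rank_by_frequency(docs, 2, stopwords = "a"), c("b", "c"))
  empty <- docs_from_counts(list())
  expect_equal(rank_by_frequency(empty, 3), character())
})

test_that("KL score matches its closed forms and is non-negative", {
  u <- uniform_reference()
  expect_equal(kl_score(u, u), 0)
  spike <- c(1, rep(0, 49))
  expect_equal(kl_score(spike, u), log(50))
  expect_error(kl_score(spike, c(0, rep(1 / 49, 49))), "infinite")

  # brute-force summation oracle on random smoothed distributions
  set.seed(7)
  for (i in 1:25) {
    p <- stats::rgamma(50, 1) + 0.01; p <- p / sum(p)
    q <- stats::rgamma(50, 1) + 0.01; q <- q / sum(q)
    oracle <- 0
    for (m in 1:50) oracle <- oracle + p[m] * log(p[m] / q[m])
    expect_equal(kl_score(p, q), oracle)
    expect_gte(kl_score(p, q), 0)
  }
})

test_that("temporal distributions pool by months-to-death and smooth", {
  docs <- tibble::tibble(
    patient_id = c("P1", "P2"),
    consult_id = 1:2,
    doc_type = "note",
    source_month = c(61L, 60L),           # months-to-death 1 and 2
    tokens = list(c("x", "x"), "x")
  )
  probs <- temporal_distributions(docs, smoothing = 1)
  expect_equal(dim(probs), c(1L, 50L))
  expect_equal(sum(probs), 1)
  expect_equal(unname(probs["x", 1]), 3 / 53)     # (2+1)/(3+50)
  expect_equal(unname(probs["x", 2]), 2 / 53)
  expect_equal(unname(probs["x", 3]), 1 / 53)
  # months before the label range are ignored
  early <- tibble::tibble(patient_id = "P", consult_id = 3L, doc_type = "note",
                          source_month = 5L, tokens = list("x"))
  expect_equal(nrow(temporal_distributions(early)), 0)
})

test_that("entropy selection ranks a planted terminal keyword above background", {
  # terminal word concentrated in the final 4 months; background uniform
  docs <- dplyr::bind_rows(
    tibble::tibble(patient_id = "P1", consult_id = 1:50, doc_type = "note",
                   source_month = 12:61,
                   tokens = lapply(1:50, function(i) "achtergrond")),
    tibble::tibble(patient_id = "P1", consult_id = 51:54, doc_type = "note",
                   source_month = 58:61, tokens = lapply(1:4, function(i)
                     rep("terminaal", 5)))
  )
  sel <- select_keywords(docs, "entropy", n = 2)
  expect_equal(sel[1], "terminaal")
  # hand-checkable ordering via kl_score on the built distributions
  probs <- temporal_distributions(docs)
  ref <- late_mass_reference()
  expect_lt(kl_score(probs["terminaal", ], ref),
            kl_score(probs["achtergrond", ], ref))
  # frequency selection ignores the temporal pattern entirely
  expect_equal(select_keywords(docs, "frequency", n = 1), "achtergrond")
  expect_equal(select_keywords(docs, "entropy", n = 0), character())
})

test_that("entropy selection recovers generator-planted keywords from a cohort", {
  cfg <- generator_config(
    n_patients = 60, seed = 21,
    signal = signal_spec(marker_penetrance = 0, keyword_ramp_start = 8,
                         keyword_ramp_peak = 0.6,
                         terminal_keywords = c("terminaal", "palliatief"))
  )
  docs <- preprocess_cohort(generate_cohort(cfg))
  top <- select_keywords(docs, "entropy", n = 5)
  expect_true(all(c("terminaal", "palliatief") %in% top))
})

test_that("embedding training respects min_count, dimension and seed", {
  set.seed(3)
  vocab <- c("hart", "longen", "maag", "pijn", "controle", "uitslag")
  docs <- tibble::tibble(
    patient_id = "P1", consult_id = 1:40, doc_type = "note",
    source_month = rep(31:40, 4),
    tokens = lapply(1:40, function(i) sample(vocab, 8, replace = TRUE))
  )
  rare <- docs
  rare$tokens[[1]] <- c(rare$tokens[[1]], rep("zeldzaam", 9))
  cfg <- embedding_config(dimensions = 100, min_count = 10, epochs = 2)
  m1 <- train_embeddings(rare, cfg, seed = 5)
  expect_false("zeldzaam" %in% rownames(m1))     # frequency 9 < 10
  expect_true(all(vocab %in% rownames(m1)))
  expect_equal(ncol(m1), 100L)
  m2 <- train_embeddings(rare, cfg, seed = 5)
  expect_identical(unclass(m1), unclass(m2))
  m3 <- train_embeddings(rare, cfg, seed = 6)
  expect_false(identical(unclass(m1), unclass(m3)))
  expect_error(train_embeddings(docs_from_counts(list(x = 2)), cfg, 1),
               "min_count")
  expect_error(embedding_config(dimensions = 64))
})

test_that("document embedding is the token mean and permutation-invariant", {
  model <- matrix(stats::rnorm(300), nrow = 3,
                  dimnames = list(c("a", "b", "c"), NULL))
  class(model) <- c("word_embeddings", "matrix", "array")
  expect_equal(embed_month_text(c("a", "a", "a"), model), unname(model["a", ]))
  expect_equal(embed_month_text(c("a", "b"), model),
               unname((model["a", ] + model["b", ]) / 2))
  expect_equal(embed_month_text(c("b", "a"), model),
               embed_month_text(c("a", "b"), model))
  expect_equal(embed_month_text(character(), model), numeric(100))
  expect_equal(embed_month_text("zzz", model), numeric(100))
})

test_that("monthly keyword counts land in the right cells", {
  docs <- tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    consult_id = 1:3,
    doc_type = "note",
    source_month = c(60L, 60L, 10L),
    tokens = list(c("pijn", "pijn", "moe"), "pijn", "moe")
  )
  arr <- keyword_month_features(docs, c("pijn", "moe"), c("P1", "P2"))
  expect_equal(dim(arr), c(61L, 2L, 2L))
  expect_equal(unname(arr[60, "pijn", "P1"]), 3)
  expect_equal(unname(arr[60, "moe", "P1"]), 1)
  expect_equal(unname(arr[10, "moe", "P2"]), 1)
  expect_equal(sum(arr), 5)
})

test_that("feature assembly concatenates and preserves structured values", {
  co <- generate_cohort(default_config(seed = 41, n_patients = 4))
  v <- build_vocabulary(co, no_cutoff_config())
  norm <- normalize_monthly(monthly_counts(co, v, no_cutoff_config()))
  docs <- preprocess_cohort(co)
  kw <- keyword_month_features(docs, c("pijn", "moe", "koorts"),
                               co$patients$patient_id)
  aug <- assemble_features(norm, kw, "keyword")
  expect_equal(dim(aug)[2], dim(norm)[2] + 3L)
  expect_identical(aug[, seq_len(dim(norm)[2]), ], norm[, , ])
  expect_true(all(aug >= 0 & aug <= 1))   # keyword block max-normalized

  emb <- array(stats::rnorm(61 * 5 * 4), c(61, 5, 4),
               dimnames = list(NULL, NULL, co$patients$patient_id))
  aug2 <- assemble_features(norm, emb, "embedding")
  passed <- aug2[, dim(norm)[2] + 1:5, ]
  dimnames(passed) <- dimnames(emb)
  expect_identical(passed, emb[, , ])  # values passed through unchanged

  bad <- kw[, , c(2, 1, 3, 4)]
  expect_error(assemble_features(norm, bad, "keyword"), "different patients")

  none <- keyword_month_features(docs, character(), co$patients$patient_id)
  expect_identical(assemble_features(norm, none, "keyword")[, , ], norm[, , ])
})
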
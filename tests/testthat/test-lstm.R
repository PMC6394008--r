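# windowed-sample container built directly from arrays
make_windows <- function(X, labels) {
  structure(list(
    x = X,
    meta = tibble::tibble(patient_id = as.character(seq_along(labels)),
                          label = as.integer(labels),
                          end_month = 61L - as.integer(labels))
  ), class = "window_set")
}

# separable toy: feature index of the label is lit across the window
toy_problem <- function(n = 400, k = 8, d = 10, t = 6, seed = 1) {
  set.seed(seed)
  y <- sample(seq_len(k), n, replace = TRUE)
  X <- array(0, c(d, t, n))
  for (s in seq_len(n)) {
    X[y[s], , s] <- 1
    X[k + 1, sample(seq_len(t), 2), s] <- stats::runif(2)
  }
  make_windows(X, y)
}

test_that("model construction is seeded and dimension-checked", {
  cfg <- model_config(seed = 11)
  m1 <- build_model(cfg, input_dim = 40)
  m2 <- build_model(cfg, input_dim = 40)
  expect_identical(m1$weights, m2$weights)
  m3 <- build_model(model_config(seed = 12), input_dim = 40)
  expect_false(identical(m1$weights, m3$weights))
  expect_equal(dim(m1$weights$W1), c(200L, 40L))
  expect_equal(dim(m1$weights$V), c(50L, 50L))
  expect_true(all(m1$weights$b1 == 0.1))
  expect_true(all(abs(m1$weights$W1) <= 0.2))  # truncated at 2 sd
  expect_error(build_model(cfg, input_dim = 0))
})

test_that("predictions are softmax distributions over the 50-month horizon", {
  cfg <- model_config(seed = 2)
  m <- build_model(cfg, input_dim = 7)
  X <- array(stats::rnorm(7 * 10 * 6), c(7, 10, 6))
  w <- make_windows(X, labels = c(1, 10, 20, 30, 40, 50))
  probs <- predict(m, w, type = "prob")
  expect_equal(dim(probs), c(6L, 50L))
  expect_equal(rowSums(probs), rep(1, 6), tolerance = 1e-6)
  expect_true(all(probs >= 0))

  # zero output layer forces the uniform distribution; argmax ties break
  # toward the earliest month
  m$weights$V[] <- 0
  m$weights$c[] <- 0
  pred <- predict(m, w)
  expect_true(all(abs(predict(m, w, type = "prob") - 0.02) < 1e-12))
  expect_equal(pred$predicted, rep(1L, 6))
  expect_equal(pred$certainty, rep(0.02, 6))
})

test_that("large keyword-scale input dimensions are accepted", {
  m <- build_model(model_config(seed = 1), input_dim = 1231)
  X <- array(stats::rnorm(1231 * 10 * 2), c(1231, 10, 2))
  probs <- predict(m, make_windows(X, c(5, 6)), type = "prob")
  expect_equal(dim(probs), c(2L, 50L))
})

test_that("analytic gradients match finite differences in both loss modes", {
  set.seed(42)
  D <- 4; T <- 3; N <- 3; H <- 5; K <- 6
  X <- array(stats::rnorm(D * T * N), c(D, T, N))
  y <- c(0L, 3L, 5L)
  m <- build_model(model_config(window = T, horizon = K, hidden_units = H,
                                seed = 9), D)
  eps <- 1e-5
  for (all_steps in c(FALSE, TRUE)) {
    g <- lifehorizon:::lstm_grad_cpp(X, y, m$weights, all_steps)
    for (nm in names(m$weights)) {
      idx <- sample(length(m$weights[[nm]]), min(6, length(m$weights[[nm]])))
      for (j in idx) {
        wp <- m$weights; wp[[nm]][j] <- wp[[nm]][j] + eps
        wm <- m$weights; wm[[nm]][j] <- wm[[nm]][j] - eps
        num <- (lifehorizon:::lstm_grad_cpp(X, y, wp, all_steps)$loss -
                  lifehorizon:::lstm_grad_cpp(X, y, wm, all_steps)$loss) /
          (2 * eps)
        expect_equal(g$grads[[nm]][j], num, tolerance = 1e-4,
                     info = paste(nm, "all_steps", all_steps))
      }
    }
  }
})

test_that("training is deterministic and the loss decreases on a separable toy", {
  w <- toy_problem()
  cfg <- model_config(window = 6, horizon = 8, hidden_units = 16,
                      learning_rate = 1e-3, epochs = 6, seed = 21)
  m1 <- train_model(build_model(cfg, 10), w)
  m2 <- train_model(build_model(cfg, 10), w)
  expect_identical(m1$weights, m2$weights)
  expect_lt(utils::tail(m1$loss_history, 1), m1$loss_history[1])
  expect_equal(length(m1$loss_history), 6L)
  acc <- mean(predict(m1, w)$predicted == w$meta$label)
  expect_gt(acc, 0.9)
})

test_that("training rejects mismatched or empty inputs", {
  w <- toy_problem(n = 20)
  cfg <- model_config(window = 6, horizon = 8, seed = 1)
  m <- build_model(cfg, input_dim = 99)
  expect_error(train_model(m, w), "input_dim")
  m2 <- build_model(model_config(window = 9, horizon = 8, seed = 1), 10)
  expect_error(train_model(m2, w), "window")
  empty <- make_windows(array(0, c(10, 6, 0)), integer())
  m3 <- build_model(cfg, input_dim = 10)
  expect_error(train_model(m3, empty), "no training samples")
})

test_that("model text serialization round-trips weights and predictions", {
  w <- toy_problem(n = 60)
  cfg <- model_config(window = 6, horizon = 8, hidden_units = 8,
                      learning_rate = 1e-3, epochs = 2, seed = 3)
  m <- train_model(build_model(cfg, 10), w)
  path <- tempfile(fileext = ".txt")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$weights, m$weights)
  expect_equal(back$config$hidden_units, 8L)
  expect_equal(predict(back, w, type = "prob"), predict(m, w, type = "prob"))
})

test_that("tidy and glance summarize a fitted model", {
  w <- toy_problem(n = 40)
  cfg <- model_config(window = 6, horizon = 8, hidden_units = 8,
                      learning_rate = 1e-3, epochs = 3, seed = 3)
  m <- train_model(build_model(cfg, 10), w)
  td <- tidy(m)
  expect_equal(td$epoch, 1:3)
  expect_true(all(is.finite(td$mean_loss)))
  gl <- glance(m)
  expect_true(gl$trained)
  expect_equal(gl$final_loss, utils::tail(m$loss_history, 1))
})
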
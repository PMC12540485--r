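make_toy_samples <- function(n, d = 8, n_areas = 3, seed = 50,
                             len_range = 2:5) {
  set.seed(seed)
  # class-informative inputs so the toy task is learnable
  protos <- matrix(rnorm(n_areas * d), n_areas, d)
  lapply(seq_len(n), function(i) {
    a <- sample.int(n_areas, 1) - 1L
    L <- sample(len_range, 1)
    rows <- matrix(rnorm(L * d, sd = 0.2), L, d) +
      matrix(protos[a + 1L, ], L, d, byrow = TRUE)
    list(rows = rows, target_area = a,
         target_quadrant = quadrant_levels()[a %% 4L + 1L],
         seq_len = L + 1L)
  })
}

test_that("positional encoding matches its closed form elementwise", {
  pe <- positional_encoding(6, 10)
  for (pos in 0:5) for (col in 1:10) {
    i2 <- 2 * (ceiling(col / 2) - 1)
    v <- pos / 10000^(i2 / 10)
    expected <- if (col %% 2 == 1) sin(v) else cos(v)
    expect_equal(pe[pos + 1, col], expected, tolerance = 1e-9)
  }
  expect_true(all(pe >= -1 & pe <= 1))
  expect_true(all(pe[1, seq(1, 9, 2)] == 0))   # sin 0
  expect_true(all(pe[1, seq(2, 10, 2)] == 1))  # cos 0
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-9)
})

test_that("scaled attention matches a scalar-loop oracle", {
  set.seed(51)
  Q <- matrix(rnorm(40), 5, 8)
  K <- matrix(rnorm(48), 6, 8)
  V <- matrix(rnorm(18), 6, 3)
  got <- scaled_attention(Q, K, V)
  # independent scalar-loop reference
  ref <- matrix(0, 5, 3)
  for (i in 1:5) {
    s <- numeric(6)
    for (j in 1:6) {
      acc <- 0
      for (k in 1:8) acc <- acc + Q[i, k] * K[j, k]
      s[j] <- acc / sqrt(8)
    }
    a <- exp(s - max(s)); a <- a / sum(a)
    for (c in 1:3) for (j in 1:6) ref[i, c] <- ref[i, c] + a[j] * V[j, c]
  }
  expect_equal(unclass(got), ref, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rowSums(attr(got, "weights")), rep(1, 5), tolerance = 1e-6)
  # a single key/value row returns that value row for any query
  one <- scaled_attention(Q, K[1, , drop = FALSE], V[1, , drop = FALSE])
  expect_equal(unclass(one), matrix(V[1, ], 5, 3, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(scaled_attention(Q, K[, 1:3], V), "key dimension")
  expect_error(scaled_attention(Q, K, V[1:2, ]), "sequence dimension")
})

test_that("cross-entropy has the textbook closed forms", {
  expect_equal(cross_entropy(matrix(0.25, 3, 4), c(1L, 2L, 4L)), log(4),
               tolerance = 1e-12)
  onehot <- diag(4)
  expect_equal(cross_entropy(onehot, 1:4), 0, tolerance = 1e-12)
})

test_that("softmax heads emit probability vectors; one class is degenerate", {
  s <- make_toy_samples(8, n_areas = 1)
  m <- fit_emotion_model(s, epochs = 1, batch_size = 8, fc_hidden = 16,
                         lstm_hidden = 8, n_heads = 2, val_samples = FALSE,
                         seed = 1)
  pr <- predict(m, s)
  expect_equal(unname(pr$area_probs[, 1]), rep(1, 8), tolerance = 1e-6)
  expect_equal(unname(rowSums(pr$quadrant_probs)), rep(1, 8), tolerance = 1e-6)
})

test_that("the default model lands near the ~470K parameter budget", {
  p <- emotraj:::.init_params(64, 4, 64, 1024, 100)
  n <- emotraj:::.n_params(p)
  expect_gte(n, 470e3 * 0.7)
  expect_lte(n, 470e3 * 1.3)
})

test_that("masked padding does not change model output", {
  s <- make_toy_samples(6, len_range = 3:3)
  m <- fit_emotion_model(s, epochs = 2, batch_size = 6, fc_hidden = 16,
                         lstm_hidden = 8, n_heads = 2, val_samples = FALSE,
                         seed = 2)
  alone <- predict(m, s[1])
  longer <- make_toy_samples(1, len_range = 9:9, seed = 99)
  padded <- predict(m, c(s[1], longer))   # batch padding forces pre-pad rows
  expect_equal(alone$area_probs[1, ], padded$area_probs[1, ], tolerance = 1e-5)
  expect_equal(alone$quadrant_probs[1, ], padded$quadrant_probs[1, ],
               tolerance = 1e-5)
})

test_that("training loss decreases on a learnable toy set", {
  s <- make_toy_samples(50)
  m <- fit_emotion_model(s, epochs = 10, batch_size = 64, fc_hidden = 32,
                         lstm_hidden = 16, n_heads = 2, dropout = 0,
                         val_samples = FALSE, seed = 3)
  loss <- m$history$train_loss
  expect_lt(loss[10], loss[1])
  expect_true(all(diff(loss) < 1e-3))  # full-batch descent: non-increasing
})

test_that("fitting is deterministic under a fixed seed", {
  s <- make_toy_samples(20)
  m1 <- fit_emotion_model(s, epochs = 2, fc_hidden = 16, lstm_hidden = 8,
                          n_heads = 2, seed = 4)
  m2 <- fit_emotion_model(s, epochs = 2, fc_hidden = 16, lstm_hidden = 8,
                          n_heads = 2, seed = 4)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("the plain-BiLSTM ablation trains and predicts", {
  s <- make_toy_samples(12)
  m <- fit_emotion_model(s, epochs = 1, fc_hidden = 16, lstm_hidden = 8,
                         n_heads = 2, use_attention = FALSE,
                         val_samples = FALSE, seed = 5)
  expect_null(m$params$attn)
  pr <- predict(m, s)
  expect_equal(unname(rowSums(pr$area_probs)), rep(1, 12), tolerance = 1e-6)
})

test_that("the joint-vertex head yields consistent marginals and tops", {
  s <- make_toy_samples(16)
  m <- fit_emotion_model(s, epochs = 2, fc_hidden = 16, lstm_hidden = 8,
                         n_heads = 2, joint_head = TRUE, val_samples = FALSE,
                         seed = 9)
  pr <- predict(m, s)
  expect_equal(unname(rowSums(pr$joint_probs)), rep(1, 16), tolerance = 1e-6)
  expect_equal(unname(rowSums(pr$area_probs)), rep(1, 16), tolerance = 1e-6)
  # marginals are exact sums of the joint distribution
  expect_equal(pr$area_probs[, 1],
               rowSums(pr$joint_probs[, 1:4]), tolerance = 1e-9)
  # top area and quadrant come from the same top joint class
  v <- max.col(pr$joint_probs, ties.method = "first") - 1L
  expect_equal(pr$top_area, v %/% 4L)
  expect_equal(pr$top_quadrant_id, v %% 4L + 1L)
})

test_that("metrics have their closed-form values on crafted predictions", {
  perfect <- structure(list(top_area = c(0L, 1L, 2L, 3L),
                            top_quadrant = quadrant_levels()),
                       class = "emotion_prediction")
  m <- emotraj:::.compute_metrics(perfect, c(0L, 1L, 2L, 3L),
                                  quadrant_levels(), seq_len = c(10, 20, 30, 40))
  expect_equal(m$joint_accuracy, 1)
  expect_equal(m$area_accuracy, 1)
  expect_equal(m$quadrant_macro$f1, 1)
  expect_equal(unname(m$per_quadrant), rep(1, 4))
  # all-one-class predictor on a balanced 4-class set
  allone <- structure(list(top_area = rep(0L, 8),
                           top_quadrant = rep("I", 8)),
                      class = "emotion_prediction")
  truth_q <- rep(quadrant_levels(), 2)
  m <- emotraj:::.compute_metrics(allone, rep(0L, 8), truth_q)
  expect_equal(m$quadrant_accuracy, 0.25)
  expect_equal(m$quadrant_macro$f1, 0.1)
  expect_equal(m$quadrant_macro$recall, 0.25)
})

test_that("k-fold cross-validation partitions, refits and averages", {
  s <- make_toy_samples(24)
  m <- fit_emotion_model(s, epochs = 2, fc_hidden = 16, lstm_hidden = 8,
                         n_heads = 2, val_samples = FALSE, seed = 6)
  # small folds may miss a quadrant; the designed warning is tested elsewhere
  ev <- suppressWarnings(evaluate_model(m, s, k_folds = 3, seed = 7))
  expect_equal(ev$k_folds, 3)
  expect_length(ev$folds, 3L)
  expect_equal(sum(vapply(ev$folds, `[[`, 0, "n")), 24)  # disjoint cover
  expect_true(ev$joint_accuracy >= 0 && ev$joint_accuracy <= 1)
  expect_equal(ev$joint_accuracy,
               mean(vapply(ev$folds, `[[`, 0, "joint_accuracy")))
})

test_that("unseen classes are dropped from macro averages with a warning", {
  pred <- structure(list(top_area = c(0L, 0L, 1L),
                         top_quadrant = c("I", "I", "II")),
                    class = "emotion_prediction")
  expect_warning(
    m <- emotraj:::.compute_metrics(pred, c(0L, 0L, 1L), c("I", "I", "II")),
    "excluded")
  expect_equal(m$quadrant_macro$f1, 1)  # over the two observed classes
})

test_that("empty sequences are rejected", {
  s <- make_toy_samples(4)
  m <- fit_emotion_model(s, epochs = 1, fc_hidden = 8, lstm_hidden = 4,
                         n_heads = 2, val_samples = FALSE, seed = 8)
  expect_error(predict(m, matrix(numeric(0), 0, 8)), "empty")
})
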
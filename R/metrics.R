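# Evaluation metrics for the joint predictor: joint and per-head accuracy,
# macro precision/recall/F1, location accuracy by true quadrant, and joint
# accuracy stratified by check-in sequence length.

.macro_prf <- function(truth, pred, classes) {
  present <- classes[classes %in% truth]
  if (length(present) < length(classes))
    warning("classes absent from truth excluded from macro average: ",
            paste(setdiff(classes, present), collapse = ", "))
  pr <- vapply(present, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }, numeric(3))
  list(precision = mean(pr[1, ]), recall = mean(pr[2, ]), f1 = mean(pr[3, ]))
}

.length_bin <- function(len) {
  b <- pmin(pmax(len %/% 10L * 10L, 10L), 50L)
  factor(b, levels = c(10L, 20L, 30L, 40L, 50L))
}

.compute_metrics <- function(pred, truth_area, truth_quad, seq_len = NULL) {
  a_ok <- pred$top_area == truth_area
  q_ok <- pred$top_quadrant == truth_quad
  out <- list(
    joint_accuracy = mean(a_ok & q_ok),
    area_accuracy = mean(a_ok),
    quadrant_accuracy = mean(q_ok),
    area_macro = .macro_prf(truth_area, pred$top_area, sort(unique(truth_area))),
    quadrant_macro = .macro_prf(truth_quad, pred$top_quadrant, quadrant_levels()),
    n = length(truth_area)
  )
  out$per_quadrant <- vapply(quadrant_levels(), function(q) {
    i <- truth_quad == q
    if (!any(i)) NA_real_ else mean(a_ok[i] & q_ok[i])
  }, 1)
  if (!is.null(seq_len)) {
    bins <- .length_bin(seq_len)
    out$per_length <- vapply(levels(bins), function(b) {
      i <- bins == b
      if (!any(i)) NA_real_ else mean(a_ok[i] & q_ok[i])
    }, 1)
  }
  out
}

# Average the class probabilities of several prediction objects (a seed
# ensemble); top classes are recomputed from the averaged distribution, via
# the joint distribution when present so the (area, quadrant) pair stays
# coherent.
.average_predictions <- function(preds) {
  avg <- function(f) Reduce(`+`, lapply(preds, `[[`, f)) / length(preds)
  out_a <- avg("area_probs"); out_q <- avg("quadrant_probs")
  if (!is.null(preds[[1]]$joint_probs)) {
    out_j <- avg("joint_probs")
    v <- max.col(out_j, ties.method = "first") - 1L
    top_a <- v %/% 4L; top_q <- v %% 4L + 1L
  } else {
    out_j <- NULL
    top_a <- max.col(out_a, ties.method = "first") - 1L
    top_q <- max.col(out_q, ties.method = "first")
  }
  structure(list(area_probs = out_a, quadrant_probs = out_q,
                 joint_probs = out_j, top_area = top_a,
                 top_quadrant = quadrant_levels()[top_q],
                 top_quadrant_id = top_q),
            class = "emotion_prediction")
}

#' Evaluate the joint predictor
#'
#' Either scores a fitted model on a held-out sample list (`k_folds = 0`) or
#' runs seeded k-fold cross-validation (refitting the model's configuration
#' on each training fold and averaging fold metrics).
#'
#' @param model Fitted `emotion_blstm`, or a list of them (a seed ensemble,
#'   scored by averaging class probabilities); for `k_folds >= 2` only the
#'   (first) model's configuration is reused.
#' @param samples List of `trajectory_matrix` samples to score.
#' @param k_folds 0 for plain holdout scoring, otherwise the number of
#'   disjoint folds covering `samples`.
#' @param seed Seed for the fold partition and per-fold refits.
#' @return List of metrics: `joint_accuracy`, `area_accuracy`,
#'   `quadrant_accuracy`, `area_macro`/`quadrant_macro`
#'   (precision/recall/F1), `per_quadrant` joint accuracy by true quadrant,
#'   `per_length` joint accuracy by sequence-length bin (10..50), and `n`.
#'   For k-fold also `folds`, the per-fold lists.
#' @export
evaluate_model <- function(model, samples, k_folds = 0, seed = 1) {
  models <- if (inherits(model, "emotion_blstm")) list(model) else model
  stopifnot(all(vapply(models, inherits, TRUE, "emotion_blstm")))
  model <- models[[1L]]
  truth_area <- vapply(samples, `[[`, 0, "target_area")
  truth_quad <- vapply(samples, `[[`, "", "target_quadrant")
  seq_len <- vapply(samples, function(s) s$seq_len %||% (nrow(s$rows) + 1L), 0)
  if (k_folds < 2) {
    pred <- .average_predictions(lapply(models, predict, samples))
    return(.compute_metrics(pred, truth_area, truth_quad, seq_len))
  }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), length(samples)))
  cfg <- model$config
  folds <- lapply(seq_len(k_folds), function(k) {
    tr <- samples[fold != k]; te <- samples[fold == k]
    m <- fit_emotion_model(tr, n_areas = cfg$n_areas, epochs = cfg$epochs,
                           batch_size = cfg$batch_size, lr = cfg$lr,
                           n_heads = cfg$n_heads, lstm_hidden = cfg$lstm_hidden,
                           fc_hidden = cfg$fc_hidden, dropout = cfg$dropout,
                           max_seq_len = cfg$max_seq_len, val_samples = FALSE,
                           use_attention = cfg$use_attention,
                           joint_head = isTRUE(cfg$joint_head),
                           weight_decay = cfg$weight_decay %||% 0,
                           seed = seed + k)
    .compute_metrics(predict(m, te),
                     truth_area[fold == k], truth_quad[fold == k],
                     seq_len[fold == k])
  })
  avg <- function(f) mean(vapply(folds, function(x) x[[f]], 1))
  out <- list(joint_accuracy = avg("joint_accuracy"),
              area_accuracy = avg("area_accuracy"),
              quadrant_accuracy = avg("quadrant_accuracy"),
              n = length(samples), k_folds = k_folds, folds = folds)
  out$per_quadrant <- rowMeans(vapply(folds, `[[`, numeric(4), "per_quadrant"),
                               na.rm = TRUE)
  out
}
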
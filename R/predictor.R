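# Joint next-area / next-quadrant predictor: sinusoidal position encoding,
# multi-head scaled dot-product attention and a BiLSTM run in parallel over
# the encoded trajectory matrix, final-step branch outputs concatenated into
# a shared fully connected trunk feeding two softmax heads. Forward pass,
# backpropagation and the Adam updates are implemented here directly in
# vectorized base R; sequences in a batch are right-aligned, pre-padded and
# masked in both branches.

#' Sinusoidal positional encoding
#'
#' `PE(pos, 2i) = sin(pos / 10000^(2i/d))`,
#' `PE(pos, 2i+1) = cos(pos / 10000^(2i/d))`, with `pos = 0 .. length - 1`
#' down the rows. Added elementwise to a trajectory matrix by the caller.
#'
#' @param length Number of sequence positions (rows).
#' @param dim Encoding dimension `d` (columns), at least 2.
#' @return `length` x `dim` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(length, dim) {
  if (length < 1L || dim < 2L) .stopf("need length >= 1 and dim >= 2")
  pos <- seq_len(length) - 1
  i2 <- 2 * (ceiling(seq_len(dim) / 2) - 1)       # 0,0,2,2,4,4,...
  ang <- outer(pos, 1 / 10000^(i2 / dim))
  pe <- matrix(0, length, dim)
  odd <- seq(1L, dim, by = 2L)                    # columns holding sin
  pe[, odd] <- sin(ang[, odd, drop = FALSE])
  if (dim > 1L) {
    even <- seq(2L, dim, by = 2L)
    pe[, even] <- cos(ang[, even, drop = FALSE])
  }
  pe
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`, softmax taken row-wise.
#'
#' @param Q,K,V Numeric matrices; `Q` and `K` share the key dimension
#'   (columns), `K` and `V` share the sequence dimension (rows).
#' @param mask Optional logical vector over key rows; `FALSE` entries are
#'   excluded from the softmax.
#' @return `nrow(Q)` x `ncol(V)` matrix; the attention weights are attached
#'   as `attr(, "weights")`.
#' @export
scaled_attention <- function(Q, K, V, mask = NULL) {
  Q <- rbind(Q); K <- rbind(K); V <- rbind(V)
  if (ncol(Q) != ncol(K)) .stopf("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) .stopf("K and V must share the sequence dimension")
  s <- Q %*% t(K) / sqrt(ncol(K))
  if (!is.null(mask)) s[, !mask] <- -Inf
  a <- .softmax_rows(s)
  structure(a %*% V, weights = a)
}

#' Cross-entropy loss
#'
#' `L = -(1/N) sum_i log p_{i, y_i}`, the multiclass cross-entropy of
#' predicted class probabilities against integer labels.
#'
#' @param probs N x C matrix of class probabilities (rows sum to 1).
#' @param labels Integer labels in `1..C`.
#' @return Mean negative log-likelihood.
#' @export
cross_entropy <- function(probs, labels) {
  probs <- rbind(probs)
  stopifnot(length(labels) == nrow(probs))
  -mean(log(pmax(probs[cbind(seq_along(labels), labels)], 1e-300)))
}

# ---- parameters ------------------------------------------------------------

.init_params <- function(d_model, n_heads, lstm_hidden, fc_hidden,
                         n_areas, use_attention = TRUE, joint_head = FALSE) {
  ru <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  }
  hh <- lstm_hidden
  lstm <- function() list(Wx = ru(d_model, 4 * hh), Wh = ru(hh, 4 * hh),
                          b = numeric(4 * hh))
  p <- list(lstm_f = lstm(), lstm_b = lstm())
  feat_dim <- 2 * hh
  if (use_attention) {
    p$attn <- list(Wq = ru(d_model, d_model), Wk = ru(d_model, d_model),
                   Wv = ru(d_model, d_model), Wo = ru(d_model, d_model),
                   bo = numeric(d_model))
    feat_dim <- feat_dim + d_model
  }
  p$trunk <- list(W1 = ru(feat_dim, fc_hidden), b1 = numeric(fc_hidden))
  if (joint_head) {
    p$head_joint <- list(W = ru(fc_hidden, n_areas * 4L),
                         b = numeric(n_areas * 4L))
  } else {
    p$head_area <- list(W = ru(fc_hidden, n_areas), b = numeric(n_areas))
    p$head_quad <- list(W = ru(fc_hidden, 4L), b = numeric(4L))
  }
  p
}

.flatten_params <- function(p) unlist(lapply(p, function(g) g), recursive = FALSE)

.n_params <- function(p) sum(vapply(.flatten_params(p), length, 1L))

# ---- batch assembly --------------------------------------------------------

# Right-aligned, zero-pre-padded batch: X is a list of T matrices (B x D),
# mask is B x T (TRUE = real step). Position encoding is added per sample
# over its own (possibly truncated) window before padding.
.make_batch <- function(samples, max_seq_len) {
  B <- length(samples)
  rows <- lapply(samples, function(s) {
    r <- s$rows
    L <- nrow(r)
    if (L > max_seq_len) r <- r[(L - max_seq_len + 1L):L, , drop = FALSE]
    # positions are anchored at the most recent step (last row = position 0),
    # so the step the prediction conditions on has a length-independent code
    r + positional_encoding(nrow(r), ncol(r))[rev(seq_len(nrow(r))), , drop = FALSE]
  })
  lens <- vapply(rows, nrow, 1L)
  Tt <- max(lens)
  D <- ncol(rows[[1L]])
  X <- lapply(seq_len(Tt), function(t) matrix(0, B, D))
  mask <- matrix(FALSE, B, Tt)
  for (b in seq_len(B)) {
    off <- Tt - lens[b]
    for (t in seq_len(lens[b])) X[[off + t]][b, ] <- rows[[b]][t, ]
    mask[b, (off + 1L):Tt] <- TRUE
  }
  list(X = X, mask = mask, B = B, Tt = Tt, D = D)
}

# ---- forward / backward ----------------------------------------------------

.forward <- function(p, batch, cfg, train = FALSE, dropout = 0) {
  B <- batch$B; Tt <- batch$Tt; D <- batch$D
  X <- batch$X; mask <- batch$mask
  mnum <- matrix(as.numeric(mask), B, Tt)
  Xflat <- do.call(rbind, X)                        # (T*B) x D, t-major blocks
  cache <- list(batch = batch, Xflat = Xflat)

  feat <- NULL
  if (!is.null(p$attn)) {
    H <- cfg$n_heads; dk <- D %/% H
    blockI <- matrix(0, D, H)
    for (h in seq_len(H)) blockI[(h - 1L) * dk + seq_len(dk), h] <- 1
    q <- X[[Tt]] %*% p$attn$Wq                      # last step is always real
    Kflat <- Xflat %*% p$attn$Wk
    Vflat <- Xflat %*% p$attn$Wv
    S <- array(0, c(B, Tt, H))
    for (t in seq_len(Tt)) {
      Kt <- Kflat[(t - 1L) * B + seq_len(B), , drop = FALSE]
      S[, t, ] <- ((q * Kt) %*% blockI) / sqrt(dk)
    }
    A <- array(0, c(B, Tt, H))
    for (h in seq_len(H)) {
      sh <- S[, , h, drop = FALSE]; dim(sh) <- c(B, Tt)
      sh[!mask] <- -Inf
      A[, , h] <- .softmax_rows(sh)
    }
    rep_head <- rep(seq_len(H), each = dk)
    Z <- matrix(0, B, D)
    for (t in seq_len(Tt)) {
      Vt <- Vflat[(t - 1L) * B + seq_len(B), , drop = FALSE]
      At <- A[, t, , drop = FALSE]; dim(At) <- c(B, H)
      Z <- Z + At[, rep_head, drop = FALSE] * Vt
    }
    attn_out <- Z %*% p$attn$Wo + rep(p$attn$bo, each = B)
    cache$attn <- list(q = q, Kflat = Kflat, Vflat = Vflat, A = A, Z = Z,
                       blockI = blockI, dk = dk, H = H, rep_head = rep_head)
    feat <- attn_out
  }

  run_lstm <- function(par, ts) {
    hh <- nrow(par$Wh)
    Gx <- Xflat %*% par$Wx + rep(par$b, each = nrow(Xflat))
    h <- matrix(0, B, hh); cc <- matrix(0, B, hh)
    steps <- vector("list", Tt)
    ii <- seq_len(hh); ff <- hh + ii; oo <- 2L * hh + ii; gg <- 3L * hh + ii
    for (t in ts) {
      gates <- Gx[(t - 1L) * B + seq_len(B), , drop = FALSE] + h %*% par$Wh
      gi <- .sigmoid(gates[, ii, drop = FALSE])
      gf <- .sigmoid(gates[, ff, drop = FALSE])
      go <- .sigmoid(gates[, oo, drop = FALSE])
      gc_ <- tanh(gates[, gg, drop = FALSE])
      c_new <- gf * cc + gi * gc_
      tc <- tanh(c_new)
      h_new <- go * tc
      mk <- mnum[, t]
      steps[[t]] <- list(gi = gi, gf = gf, go = go, gc = gc_,
                         c_prev = cc, tc = tc, h_prev = h, mk = mk)
      h <- mk * h_new + (1 - mk) * h
      cc <- mk * c_new + (1 - mk) * cc
    }
    list(h = h, steps = steps, Gx = Gx, hh = hh, ts = ts)
  }
  fwd <- run_lstm(p$lstm_f, seq_len(Tt))
  bwd <- run_lstm(p$lstm_b, rev(seq_len(Tt)))
  cache$fwd <- fwd; cache$bwd <- bwd
  feat <- if (is.null(feat)) cbind(fwd$h, bwd$h) else cbind(feat, fwd$h, bwd$h)
  cache$feat <- feat

  pre <- feat %*% p$trunk$W1 + rep(p$trunk$b1, each = B)
  hid <- pmax(pre, 0)
  drop <- NULL
  if (train && dropout > 0) {
    drop <- matrix(stats::runif(length(hid)) >= dropout, nrow(hid)) / (1 - dropout)
    hid <- hid * drop
  }
  cache$pre <- pre; cache$hid <- hid; cache$drop <- drop

  if (!is.null(p$head_joint)) {
    # one softmax over (area, quadrant) vertex classes, quadrant-minor order;
    # head probabilities are its marginals
    lj <- hid %*% p$head_joint$W + rep(p$head_joint$b, each = B)
    pj <- .softmax_rows(lj)
    n_areas <- ncol(pj) %/% 4L
    cache$joint_probs <- pj
    cache$area_probs <- pj %*% (diag(n_areas)[rep(seq_len(n_areas), each = 4L), ])
    cache$quad_probs <- pj %*% (diag(4L)[rep.int(seq_len(4L), n_areas), ])
  } else {
    la <- hid %*% p$head_area$W + rep(p$head_area$b, each = B)
    lq <- hid %*% p$head_quad$W + rep(p$head_quad$b, each = B)
    cache$area_probs <- .softmax_rows(la)
    cache$quad_probs <- .softmax_rows(lq)
  }
  cache
}

.backward <- function(p, cache, y_area, y_quad, cfg) {
  batch <- cache$batch
  B <- batch$B; Tt <- batch$Tt; D <- batch$D
  mask <- batch$mask
  mnum <- matrix(as.numeric(mask), B, Tt)
  g <- list()

  if (!is.null(p$head_joint)) {
    y_joint <- (y_area - 1L) * 4L + y_quad
    dlj <- cache$joint_probs
    dlj[cbind(seq_len(B), y_joint)] <- dlj[cbind(seq_len(B), y_joint)] - 1
    dlj <- dlj / B
    g$head_joint <- list(W = t(cache$hid) %*% dlj, b = colSums(dlj))
    dhid <- dlj %*% t(p$head_joint$W)
  } else {
    dla <- cache$area_probs
    dla[cbind(seq_len(B), y_area)] <- dla[cbind(seq_len(B), y_area)] - 1
    dla <- dla / B
    dlq <- cache$quad_probs
    dlq[cbind(seq_len(B), y_quad)] <- dlq[cbind(seq_len(B), y_quad)] - 1
    dlq <- dlq / B
    g$head_area <- list(W = t(cache$hid) %*% dla, b = colSums(dla))
    g$head_quad <- list(W = t(cache$hid) %*% dlq, b = colSums(dlq))
    dhid <- dla %*% t(p$head_area$W) + dlq %*% t(p$head_quad$W)
  }
  if (!is.null(cache$drop)) dhid <- dhid * cache$drop
  dpre <- dhid * (cache$pre > 0)
  g$trunk <- list(W1 = t(cache$feat) %*% dpre, b1 = colSums(dpre))
  dfeat <- dpre %*% t(p$trunk$W1)

  off <- 0L
  d_attn <- NULL
  if (!is.null(p$attn)) {
    d_attn <- dfeat[, seq_len(D), drop = FALSE]
    off <- D
  }
  hh <- cache$fwd$hh
  dh_f <- dfeat[, off + seq_len(hh), drop = FALSE]
  dh_b <- dfeat[, off + hh + seq_len(hh), drop = FALSE]

  if (!is.null(p$attn)) {
    at <- cache$attn
    H <- at$H; dk <- at$dk; rep_head <- at$rep_head
    g$attn <- list(Wo = t(at$Z) %*% d_attn, bo = colSums(d_attn))
    dZ <- d_attn %*% t(p$attn$Wo)
    dA <- array(0, c(B, Tt, H))
    dVflat <- matrix(0, Tt * B, D)
    for (t in seq_len(Tt)) {
      idx <- (t - 1L) * B + seq_len(B)
      Vt <- at$Vflat[idx, , drop = FALSE]
      At <- at$A[, t, , drop = FALSE]; dim(At) <- c(B, H)
      dVflat[idx, ] <- At[, rep_head, drop = FALSE] * dZ
      dA[, t, ] <- (dZ * Vt) %*% at$blockI
    }
    dS <- array(0, c(B, Tt, H))
    for (h in seq_len(H)) {
      Ah <- at$A[, , h, drop = FALSE]; dim(Ah) <- c(B, Tt)
      dAh <- dA[, , h, drop = FALSE]; dim(dAh) <- c(B, Tt)
      dS[, , h] <- Ah * (dAh - rowSums(Ah * dAh))
    }
    dq <- matrix(0, B, D)
    dKflat <- matrix(0, Tt * B, D)
    for (t in seq_len(Tt)) {
      idx <- (t - 1L) * B + seq_len(B)
      Kt <- at$Kflat[idx, , drop = FALSE]
      dSt <- dS[, t, , drop = FALSE]; dim(dSt) <- c(B, H)
      dSexp <- dSt[, rep_head, drop = FALSE] / sqrt(dk)
      dq <- dq + dSexp * Kt
      dKflat[idx, ] <- dSexp * at$q
    }
    g$attn$Wq <- t(batch$X[[Tt]]) %*% dq
    g$attn$Wk <- t(cache$Xflat) %*% dKflat
    g$attn$Wv <- t(cache$Xflat) %*% dVflat
  }

  back_lstm <- function(par, run, dh_final) {
    hh <- run$hh
    ii <- seq_len(hh); ff <- hh + ii; oo <- 2L * hh + ii; gg <- 3L * hh + ii
    dh <- dh_final; dc <- matrix(0, B, hh)
    dGx <- matrix(0, Tt * B, 4L * hh)
    dWh <- matrix(0, hh, 4L * hh)
    for (t in rev(run$ts)) {
      st <- run$steps[[t]]
      mk <- st$mk
      dh_eff <- dh * mk; dc_eff <- dc * mk
      carry_dh <- dh * (1 - mk); carry_dc <- dc * (1 - mk)
      do_ <- dh_eff * st$tc
      dct <- dc_eff + dh_eff * st$go * (1 - st$tc^2)
      dgates <- cbind(dct * st$gc * st$gi * (1 - st$gi),
                      dct * st$c_prev * st$gf * (1 - st$gf),
                      do_ * st$go * (1 - st$go),
                      dct * st$gi * (1 - st$gc^2))
      dGx[(t - 1L) * B + seq_len(B), ] <- dgates
      dWh <- dWh + t(st$h_prev) %*% dgates
      dh <- dgates %*% t(par$Wh) + carry_dh
      dc <- dct * st$gf + carry_dc
    }
    list(Wx = t(cache$Xflat) %*% dGx, Wh = dWh, b = colSums(dGx))
  }
  g$lstm_f <- back_lstm(p$lstm_f, cache$fwd, dh_f)
  g$lstm_b <- back_lstm(p$lstm_b, cache$bwd, dh_b)
  g
}

.adam_step <- function(p, g, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (grp in names(g)) for (nm in names(g[[grp]])) {
    gr <- g[[grp]][[nm]]
    key <- paste(grp, nm)
    m <- state$m[[key]] %||% 0
    v <- state$v[[key]] %||% 0
    m <- beta1 * m + (1 - beta1) * gr
    v <- beta2 * v + (1 - beta2) * gr^2
    state$m[[key]] <- m
    state$v[[key]] <- v
    upd <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    if (weight_decay > 0 && nm %in% c("W", "W1", "Wx", "Wh", "Wq", "Wk", "Wv", "Wo"))
      upd <- upd + lr * weight_decay * p[[grp]][[nm]]   # decoupled decay
    p[[grp]][[nm]] <- p[[grp]][[nm]] - upd
  }
  list(p = p, state = state)
}

# ---- fitting ---------------------------------------------------------------

#' Fit the attention-BiLSTM location-emotion predictor
#'
#' Trains the joint next-stay-area / next-quadrant model on trajectory
#' matrices. The loss is the sum of the two heads' cross-entropies; training
#' uses mini-batch Adam under a fixed seed (identical seed and data give an
#' identical model). When no validation set is supplied, 20% of the samples
#' are held out at random for per-epoch validation metrics.
#'
#' @param samples List of `trajectory_matrix` samples (see
#'   [trajectory_matrix()] / [make_training_samples()]).
#' @param n_areas Number of location classes; defaults to
#'   `max(target_area) + 1` over the samples.
#' @param epochs Training epochs (default 256).
#' @param batch_size Mini-batch size (default 64).
#' @param lr Adam learning rate.
#' @param n_heads Attention heads; must divide the embedding dimension.
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param fc_hidden Width of the shared fully connected trunk.
#' @param dropout Dropout rate on the trunk (training only).
#' @param weight_decay Decoupled L2 decay applied to weight matrices (not
#'   biases) at each Adam step; 0 disables it.
#' @param max_seq_len Maximum window length; longer inputs keep their most
#'   recent `max_seq_len` steps.
#' @param val_samples Optional explicit validation list; `NULL` means an
#'   internal random 80/20 split, `FALSE` disables validation.
#' @param keep_best Return the parameters from the epoch with the best
#'   validation joint accuracy instead of the last epoch (needs validation
#'   samples; guards against overfitting past the optimum).
#' @param use_attention Set `FALSE` for the plain-BiLSTM ablation.
#' @param joint_head Use a single softmax over the `n_areas * 4`
#'   (area, quadrant) vertex classes instead of two marginal heads; the
#'   reported head probabilities are then its marginals and the top
#'   predictions come from the top joint class, which keeps the
#'   (area, quadrant) pair consistent.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return Object of class `emotion_blstm` with elements `params`, `config`,
#'   `history` (per-epoch data.frame), `n_parameters`.
#' @export
fit_emotion_model <- function(samples, n_areas = NULL, epochs = 256,
                              batch_size = 64, lr = 1e-3, n_heads = 4,
                              lstm_hidden = 64, fc_hidden = 1024,
                              dropout = 0.1, max_seq_len = 20,
                              val_samples = NULL, use_attention = TRUE,
                              joint_head = FALSE, keep_best = FALSE,
                              weight_decay = 0, seed = 1, verbose = FALSE) {
  if (length(samples) < 2L) .stopf("need at least 2 training samples")
  d_model <- ncol(samples[[1L]]$rows)
  if (d_model %% n_heads != 0L) .stopf("d_model (%d) not divisible by n_heads (%d)",
                                       d_model, n_heads)
  areas <- vapply(samples, `[[`, 0, "target_area")
  if (is.null(n_areas)) n_areas <- max(areas) + 1L
  quads <- match(vapply(samples, `[[`, "", "target_quadrant"), quadrant_levels())
  if (anyNA(quads)) .stopf("unknown quadrant label in samples")

  set.seed(seed)
  internal_val <- is.null(val_samples)
  if (internal_val) {
    n_val <- max(1L, round(0.2 * length(samples)))
    vi <- sample(length(samples), n_val)
    val_samples <- samples[vi]
    samples <- samples[-vi]
    areas <- areas[-vi]; quads <- quads[-vi]
  } else if (isFALSE(val_samples)) val_samples <- NULL

  cfg <- list(d_model = d_model, n_heads = n_heads, lstm_hidden = lstm_hidden,
              fc_hidden = fc_hidden, n_areas = n_areas, dropout = dropout,
              max_seq_len = max_seq_len, batch_size = batch_size, lr = lr,
              epochs = epochs, use_attention = use_attention,
              joint_head = joint_head, weight_decay = weight_decay,
              seed = seed)
  p <- .init_params(d_model, n_heads, lstm_hidden, fc_hidden, n_areas,
                    use_attention, joint_head)
  state <- list(t = 0L, m = list(), v = list())
  lens <- vapply(samples, function(s) min(nrow(s$rows), max_seq_len), 0)
  n <- length(samples)
  hist <- vector("list", epochs)
  best <- list(acc = -Inf, params = NULL, epoch = NA_integer_)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    ord <- ord[order(lens[ord])]          # stable: shuffles within a length
    tot <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      batch <- .make_batch(samples[idx], max_seq_len)
      cache <- .forward(p, batch, cfg, train = TRUE, dropout = dropout)
      ya <- areas[idx] + 1L; yq <- quads[idx]
      loss <- if (joint_head)
        cross_entropy(cache$joint_probs, (ya - 1L) * 4L + yq)
      else
        cross_entropy(cache$area_probs, ya) + cross_entropy(cache$quad_probs, yq)
      if (!is.finite(loss))
        .stopf("non-finite loss at epoch %d (lr too high or bad inputs)", ep)
      g <- .backward(p, cache, ya, yq, cfg)
      upd <- .adam_step(p, g, state, lr, weight_decay)
      p <- upd$p; state <- upd$state
      tot <- tot + loss * length(idx); nb <- nb + length(idx)
    }
    row <- data.frame(epoch = ep, train_loss = tot / nb,
                      val_loss = NA_real_, val_joint_accuracy = NA_real_)
    if (!is.null(val_samples) && length(val_samples)) {
      model_tmp <- structure(list(params = p, config = cfg), class = "emotion_blstm")
      pr <- predict(model_tmp, val_samples)
      va <- vapply(val_samples, `[[`, 0, "target_area") + 1L
      vq <- match(vapply(val_samples, `[[`, "", "target_quadrant"), quadrant_levels())
      row$val_loss <- cross_entropy(pr$area_probs, va) +
        cross_entropy(pr$quadrant_probs, vq)
      row$val_joint_accuracy <- mean(pr$top_area + 1L == va & pr$top_quadrant_id == vq)
      if (keep_best && row$val_joint_accuracy > best$acc)
        best <- list(acc = row$val_joint_accuracy, params = p, epoch = ep)
    }
    hist[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  val joint acc %.3f",
                      ep, row$train_loss, row$val_loss, row$val_joint_accuracy))
  }
  best_epoch <- NA_integer_
  if (keep_best && !is.null(best$params)) {
    p <- best$params
    best_epoch <- best$epoch
  }
  structure(list(params = p, config = cfg,
                 history = do.call(rbind, hist),
                 n_parameters = .n_params(p), best_epoch = best_epoch,
                 val_samples = if (internal_val) val_samples else NULL),
            class = "emotion_blstm")
}

#' Predict next stay area and emotional quadrant
#'
#' @param object Fitted `emotion_blstm`.
#' @param newdata A `trajectory_matrix`, a plain numeric matrix of embedding
#'   rows, or a list of either.
#' @param ... Unused.
#' @return Object of class `emotion_prediction`: `area_probs` (N x n_areas),
#'   `quadrant_probs` (N x 4), `top_area` (0-based area ids),
#'   `top_quadrant` (labels), `top_quadrant_id`.
#' @export
predict.emotion_blstm <- function(object, newdata, ...) {
  if (inherits(newdata, "trajectory_matrix") ||
      (is.matrix(newdata) && is.numeric(newdata)))
    newdata <- list(newdata)
  newdata <- lapply(newdata, function(s)
    if (is.matrix(s)) list(rows = s) else s)
  for (s in newdata)
    if (nrow(s$rows) < 1L) .stopf("empty input sequence")
  cfg <- object$config
  out_a <- NULL; out_q <- NULL; out_j <- NULL
  for (b0 in seq(1L, length(newdata), by = cfg$batch_size)) {
    idx <- b0:min(b0 + cfg$batch_size - 1L, length(newdata))
    batch <- .make_batch(newdata[idx], cfg$max_seq_len)
    cache <- .forward(object$params, batch, cfg, train = FALSE)
    out_a <- rbind(out_a, cache$area_probs)
    out_q <- rbind(out_q, cache$quad_probs)
    if (!is.null(cache$joint_probs)) out_j <- rbind(out_j, cache$joint_probs)
  }
  colnames(out_q) <- quadrant_levels()
  if (is.null(out_j)) {
    top_a <- max.col(out_a, ties.method = "first") - 1L
    top_q <- max.col(out_q, ties.method = "first")
  } else {
    v <- max.col(out_j, ties.method = "first") - 1L
    top_a <- v %/% 4L
    top_q <- v %% 4L + 1L
  }
  structure(list(area_probs = out_a, quadrant_probs = out_q,
                 joint_probs = out_j,
                 top_area = top_a,
                 top_quadrant = quadrant_levels()[top_q],
                 top_quadrant_id = top_q),
            class = "emotion_prediction")
}

#' @export
print.emotion_blstm <- function(x, ...) {
  cfg <- x$config
  cat("Attention-BiLSTM location-emotion predictor\n")
  cat(sprintf("  input dim %d | %d heads | LSTM hidden %d/dir | trunk %d\n",
              cfg$d_model, cfg$n_heads, cfg$lstm_hidden, cfg$fc_hidden))
  cat(sprintf("  classes: %d stay areas x 4 quadrants | %s parameters\n",
              cfg$n_areas, format(x$n_parameters, big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs | final train loss %.4f\n",
                nrow(x$history), utils::tail(x$history$train_loss, 1)))
  invisible(x)
}

#' @export
summary.emotion_blstm <- function(object, ...) {
  print(object)
  h <- object$history
  if (!is.null(h) && any(is.finite(h$val_joint_accuracy)))
    cat(sprintf("  final validation joint accuracy %.3f\n",
                utils::tail(h$val_joint_accuracy[is.finite(h$val_joint_accuracy)], 1)))
  invisible(object)
}

#' @export
coef.emotion_blstm <- function(object, ...) object$params

#' @export
plot.emotion_blstm <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training history", ...)
  if (any(is.finite(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  invisible(x)
}
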
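# Proximity-preserving vertex embedding of the interaction graph, in the
# LINE family: first-order proximity ties directly connected vertices,
# second-order proximity ties vertices with similar out-neighborhoods.
# Trained by weighted edge sampling with negative sampling; mini-batch
# gradients are aggregated per vertex (rowsum) before each update, which
# keeps the optimization deterministic under a fixed seed and fast in R.

# Exact second-order objective on a dense graph (used for gradient checks):
# O2 = -sum_{(i,j) in E} w_ij * log softmax_j(u_i . c_j).
.line_o2_value <- function(u, ctx, edges) {
  s <- u %*% t(ctx)
  logz <- log(rowSums(exp(s)))
  -sum(edges$w * (s[cbind(edges$i, edges$j)] - logz[edges$i]))
}

.line_o2_grad <- function(u, ctx, edges) {
  n <- nrow(u)
  s <- u %*% t(ctx)
  p <- .softmax_rows(s)
  e <- matrix(0, n, n)
  for (r in seq_len(nrow(edges)))
    e[edges$i[r], edges$j[r]] <- e[edges$i[r], edges$j[r]] + edges$w[r]
  wsrc <- rowSums(e)
  ds <- e - wsrc * p            # d(-O2)/dS
  list(du = -(ds %*% ctx), dctx = -(t(ds) %*% u))
}

.line_train_order <- function(n_v, src, dst, w, out_deg, dim, order1,
                              n_samples, n_negative, lr, batch_size) {
  u <- matrix(stats::runif(n_v * dim, -0.5 / dim, 0.5 / dim), n_v, dim)
  ctx <- if (order1) NULL else matrix(0, n_v, dim)
  negp <- out_deg^0.75
  if (sum(negp) <= 0) .stopf("graph has no outgoing weight")
  n_e <- length(w)
  done <- 0
  lr_min <- 1e-4
  while (done < n_samples) {
    bs <- min(batch_size, n_samples - done)
    frac <- done / n_samples
    lr_t <- lr * (1 - frac) + lr_min * frac
    ei <- sample.int(n_e, bs, replace = TRUE, prob = w)
    i <- src[ei]; j <- dst[ei]
    neg <- sample.int(n_v, bs * n_negative, replace = TRUE, prob = negp)
    i_rep <- rep(i, times = n_negative)
    tgt <- if (order1) u else ctx
    g_pos <- 1 - .sigmoid(rowSums(u[i, , drop = FALSE] * tgt[j, , drop = FALSE]))
    g_neg <- -.sigmoid(rowSums(u[i_rep, , drop = FALSE] * tgt[neg, , drop = FALSE]))
    # a negative draw that hits the true target (or the source itself for the
    # shared first-order table) would cancel the positive signal; skip it
    j_rep <- rep(j, times = n_negative)
    skip <- neg == j_rep
    if (order1) skip <- skip | neg == i_rep
    g_neg[skip] <- 0
    d_src <- rbind(g_pos * tgt[j, , drop = FALSE],
                   g_neg * tgt[neg, , drop = FALSE])
    d_tgt <- rbind(g_pos * u[i, , drop = FALSE],
                   g_neg * u[i_rep, , drop = FALSE])
    if (order1) {
      agg <- rowsum(rbind(d_src, d_tgt), c(i, i_rep, j, neg))
      rid <- as.integer(rownames(agg))
      u[rid, ] <- u[rid, ] + lr_t * agg
    } else {
      agg <- rowsum(d_src, c(i, i_rep))
      rid <- as.integer(rownames(agg))
      u[rid, ] <- u[rid, ] + lr_t * agg
      agg <- rowsum(d_tgt, c(j, neg))
      rid <- as.integer(rownames(agg))
      ctx[rid, ] <- ctx[rid, ] + lr_t * agg
    }
    done <- done + bs
  }
  u
}

#' Embed interaction-graph vertices
#'
#' Learns a low-dimensional vector per (stay area, quadrant) vertex that
#' preserves first- and/or second-order proximity of the weighted directed
#' graph. Edges are sampled proportional to weight; negatives are drawn from
#' the weighted out-degree raised to 3/4. With `order = "both"` the two
#' objectives are trained independently on `dim/2` coordinates each and
#' concatenated.
#'
#' @param graph An `emotion_graph`.
#' @param dim Embedding dimension (even when `order = "both"`); default 64.
#' @param order `"both"`, `"first"` or `"second"`.
#' @param n_samples Total edge samples per order (default 1e5).
#' @param n_negative Negative samples per positive (default 5).
#' @param lr Initial learning rate, decayed linearly to 1e-4.
#' @param batch_size Edge samples per aggregated update.
#' @param seed RNG seed; fixed seed gives a bitwise-identical table.
#' @return Numeric matrix, one row per vertex (rownames are
#'   `"<area>:<quadrant>"` keys). Vertices with no incident edge keep their
#'   random initialization and are listed in `attr(, "untrained")`.
#' @export
line_embed <- function(graph, dim = 64, order = c("both", "first", "second"),
                       n_samples = 1e5, n_negative = 5, lr = 0.025,
                       batch_size = 128, seed = NULL) {
  stopifnot(inherits(graph, "emotion_graph"))
  order <- match.arg(order)
  verts <- graph$vertices
  n_v <- length(verts)
  if (n_v < 2L || nrow(graph$edges) < 1L)
    .stopf("graph needs >= 2 vertices and >= 1 edge")
  if (order == "both" && dim %% 2L != 0L) .stopf("dim must be even for order='both'")
  if (n_samples <= 0) .stopf("n_samples must be > 0")
  if (!is.null(seed)) set.seed(seed)
  src <- match(.vertex_key(graph$edges$src_area, graph$edges$src_quadrant), verts)
  dst <- match(.vertex_key(graph$edges$dst_area, graph$edges$dst_quadrant), verts)
  w <- graph$edges$weight
  out_deg <- as.numeric(graph$out_degree[verts])
  run <- function(ord1, d) .line_train_order(n_v, src, dst, w, out_deg, d,
                                             ord1, n_samples, n_negative,
                                             lr, batch_size)
  tab <- switch(order,
                first  = run(TRUE, dim),
                second = run(FALSE, dim),
                both   = cbind(run(TRUE, dim %/% 2L), run(FALSE, dim %/% 2L)))
  rownames(tab) <- verts
  untrained <- setdiff(verts, verts[unique(c(src, dst))])
  attr(tab, "untrained") <- untrained
  .assert_finite(tab, "embedding table")
  tab
}

#' Build one user's trajectory matrix
#'
#' Stacks the embeddings of the user's first `m - 1` steps in time order;
#' the m-th step's (area, quadrant) is the prediction target.
#'
#' @param traj A `user_trajectory` with `m >= 2` steps.
#' @param table Embedding table from [line_embed()].
#' @return List of class `trajectory_matrix`: `rows` ((m-1) x d matrix),
#'   `target_area`, `target_quadrant`, `user_id`, `seq_len` (= m).
#' @export
trajectory_matrix <- function(traj, table) {
  stopifnot(inherits(traj, "user_trajectory"))
  m <- length(traj$t)
  if (m < 2L) .stopf("trajectory needs at least 2 steps, got %d", m)
  miss <- setdiff(traj$key, rownames(table))
  if (length(miss)) .stopf("vertex not in embedding table: %s", miss[1])
  rows <- table[traj$key[-m], , drop = FALSE]
  structure(list(rows = rows,
                 target_area = traj$area[m],
                 target_quadrant = traj$quadrant[m],
                 user_id = traj$user_id, seq_len = m),
            class = "trajectory_matrix")
}

#' Expand trajectories into sliding-window training samples
#'
#' For each trajectory step `j >= 2`, the most recent `max_len` preceding
#' steps form one sample whose target is step `j`; the final window
#' (`j = m`) is exactly [trajectory_matrix()] truncated to `max_len` rows.
#' `seq_len` records `j`, the number of check-ins up to and including the
#' target, which is the stratification variable for length-binned accuracy.
#'
#' @param trajectories List of `user_trajectory` objects.
#' @param table Embedding table.
#' @param max_len Maximum window length (rows) per sample.
#' @return List of `trajectory_matrix`-shaped samples.
#' @export
make_training_samples <- function(trajectories, table, max_len = 20L) {
  out <- list()
  for (tr in trajectories) {
    m <- length(tr$t)
    if (m < 2L) next
    miss <- setdiff(tr$key, rownames(table))
    if (length(miss)) .stopf("vertex not in embedding table: %s", miss[1])
    emb <- table[tr$key, , drop = FALSE]
    for (j in 2:m) {
      lo <- max(1L, j - max_len)
      out[[length(out) + 1L]] <-
        structure(list(rows = emb[lo:(j - 1L), , drop = FALSE],
                       target_area = tr$area[j],
                       target_quadrant = tr$quadrant[j],
                       user_id = tr$user_id, seq_len = j),
                  class = "trajectory_matrix")
    }
  }
  out
}
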
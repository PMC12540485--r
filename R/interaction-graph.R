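# The emotional interaction graph: vertices are (stay area, quadrant)
# states; each consecutive pair of one user's check-ins contributes a
# directed edge whose weight decays with the inter-post gap, normalized by
# that user's largest gap.

.vertex_key <- function(area, quadrant) paste0(area, ":", quadrant)

#' Build one user's (vertex, time) trajectory
#'
#' Drops noise check-ins (area `NA`), collapses equal timestamps by shifting
#' the later post in file order forward by one second (repeatedly, so times
#' end up strictly increasing).
#'
#' @param t Timestamps (epoch seconds) in file order.
#' @param area Area id per check-in (`NA` = noise).
#' @param quadrant Quadrant label per check-in.
#' @param user_id User identifier carried on the result.
#' @return List of class `user_trajectory`: `user_id`, `area`, `quadrant`,
#'   `key` (vertex key), `t`; `usable` is `TRUE` when at least two steps
#'   survive (needed to contribute edges).
#' @export
build_trajectory <- function(t, area, quadrant, user_id = NA_character_) {
  keep <- !is.na(area)
  t <- as.numeric(t[keep]); area <- area[keep]; quadrant <- quadrant[keep]
  ord <- order(t)  # stable: ties keep file order
  t <- t[ord]; area <- area[ord]; quadrant <- quadrant[ord]
  if (length(t) > 1L)
    for (i in 2:length(t)) if (t[i] <= t[i - 1L]) t[i] <- t[i - 1L] + 1
  structure(list(user_id = user_id, area = area, quadrant = quadrant,
                 key = .vertex_key(area, quadrant), t = t,
                 usable = length(t) >= 2L),
            class = "user_trajectory")
}

#' Time-decay weight of one trajectory edge
#'
#' `g(dt) = 1 / (1 + exp(-t_max / (alpha * dt)))`, the logistic function of
#' the user's largest inter-post gap over `alpha` times this gap: short gaps
#' bind consecutive states strongly. Strictly decreasing in `dt`, with range
#' (0.5, 1).
#'
#' @param dt Inter-post gap, seconds (> 0); vectorized.
#' @param t_max The user's maximum inter-post gap, seconds (> 0).
#' @param alpha Decay regulator, default 10.
#' @return Weights in (0.5, 1).
#' @export
edge_weight <- function(dt, t_max, alpha = 10) {
  if (any(!is.finite(dt) | dt <= 0)) .stopf("dt must be > 0")
  if (!is.finite(t_max) || t_max <= 0) .stopf("t_max must be > 0")
  if (!is.finite(alpha) || alpha <= 0) .stopf("alpha must be > 0")
  stats::plogis(t_max / (alpha * dt))
}

.make_graph <- function(edges) {
  vk_src <- .vertex_key(edges$src_area, edges$src_quadrant)
  vk_dst <- .vertex_key(edges$dst_area, edges$dst_quadrant)
  vertices <- sort(unique(c(vk_src, vk_dst)))
  out_degree <- structure(numeric(length(vertices)), names = vertices)
  agg <- rowsum(edges$weight, vk_src)
  out_degree[rownames(agg)] <- agg[, 1]
  structure(list(edges = edges, vertices = vertices, out_degree = out_degree),
            class = "emotion_graph")
}

#' Build the emotional interaction graph from user trajectories
#'
#' Every consecutive pair in every usable trajectory contributes a directed
#' edge; per-user weights use that user's maximum gap as `t_max` and are
#' summed over users. Self-loops (staying in the same state) are kept.
#'
#' @param trajectories List of `user_trajectory` objects.
#' @param alpha Decay regulator for [edge_weight()].
#' @param extra_vertices Optional character keys to include as isolated
#'   vertices (e.g. trajectory endpoints with no outgoing edge are included
#'   automatically).
#' @return An `emotion_graph`: `edges` (data.frame `src_area src_quadrant
#'   dst_area dst_quadrant weight`), `vertices` (keys), `out_degree`
#'   (named, weighted).
#' @export
build_graph <- function(trajectories, alpha = 10, extra_vertices = NULL) {
  trajectories <- Filter(function(tr) isTRUE(tr$usable), trajectories)
  if (!length(trajectories)) .stopf("no usable trajectories (need >= 2 steps)")
  src <- dst <- character(0); w <- numeric(0)
  for (tr in trajectories) {
    m <- length(tr$t)
    dt <- diff(tr$t)
    t_max <- max(dt)
    w <- c(w, edge_weight(dt, t_max, alpha))
    src <- c(src, tr$key[-m])
    dst <- c(dst, tr$key[-1L])
  }
  pair <- paste(src, dst, sep = ">")
  agg <- rowsum(w, pair)
  sp <- strsplit(rownames(agg), ">", fixed = TRUE)
  sk <- do.call(rbind, strsplit(vapply(sp, `[`, "", 1L), ":", fixed = TRUE))
  dk <- do.call(rbind, strsplit(vapply(sp, `[`, "", 2L), ":", fixed = TRUE))
  edges <- data.frame(src_area = as.integer(sk[, 1]), src_quadrant = sk[, 2],
                      dst_area = as.integer(dk[, 1]), dst_quadrant = dk[, 2],
                      weight = agg[, 1])
  edges <- edges[order(edges$src_area, edges$src_quadrant,
                       edges$dst_area, edges$dst_quadrant), , drop = FALSE]
  rownames(edges) <- NULL
  g <- .make_graph(edges)
  allv <- sort(unique(c(g$vertices, unlist(lapply(trajectories, `[[`, "key")),
                        extra_vertices)))
  miss <- setdiff(allv, g$vertices)
  if (length(miss)) {
    g$vertices <- allv
    od <- structure(numeric(length(allv)), names = allv)
    od[names(g$out_degree)] <- g$out_degree
    g$out_degree <- od
  }
  g
}

#' Split labeled, clustered check-ins into per-user trajectories
#'
#' @param checkins Labeled check-ins (columns `user_id`, `t`, `quadrant`).
#' @param assignments Area id per check-in (`NA` = noise), aligned by row.
#' @return Named list of `user_trajectory` objects, one per user, in order
#'   of first appearance.
#' @export
build_trajectories <- function(checkins, assignments) {
  stopifnot(nrow(checkins) == length(assignments))
  uids <- unique(checkins$user_id)
  out <- lapply(uids, function(u) {
    i <- which(checkins$user_id == u)
    build_trajectory(checkins$t[i], assignments[i], checkins$quadrant[i], u)
  })
  names(out) <- uids
  out
}
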
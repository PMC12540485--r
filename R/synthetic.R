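# Seeded generator of geotagged emotional check-ins with known ground
# truth. Users walk a first-order Markov chain over (stay area, quadrant)
# states; the designated successor of each state carries `stickiness`
# probability, so the optimal predictor's accuracy (the Bayes rate) is
# computable in closed form and equals the stickiness.

.quad_signs <- matrix(c(1, 1, -1, 1, -1, -1, 1, -1), 4, 2, byrow = TRUE,
                      dimnames = list(c("I", "II", "III", "IV"), c("x", "y")))

.stationary <- function(P, tol = 1e-12, iter = 2000L) {
  pi <- rep(1 / nrow(P), nrow(P))
  for (k in seq_len(iter)) {
    nxt <- as.numeric(pi %*% P)
    if (max(abs(nxt - pi)) < tol) return(nxt / sum(nxt))
    pi <- nxt
  }
  pi / sum(pi)
}

#' Simulate a synthetic check-in world
#'
#' Lays out stay-area centers in a bounding box (minimum 2 km separation)
#' and builds a first-order transition matrix over the
#' `n_areas * 4` (area, quadrant) states. Each state's designated successor
#' carries probability `stickiness`; the remaining mass is spread over the
#' other states, uniform across areas and proportional to `quadrant_mix`
#' across quadrants, so the chain's stationary quadrant marginal matches the
#' configured imbalance (the default mix puts 73.4% of mass on the positive
#' quadrants I and IV). Successor draws are re-sampled until the stationary
#' marginal is within 0.05 of `quadrant_mix`.
#'
#' @param n_areas Number of stay areas.
#' @param n_users Number of users (stored for [simulate_users()]).
#' @param area_centers Optional matrix of (lon, lat) centers; default random
#'   in `bbox`.
#' @param bbox Bounding box `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param area_sigma Gaussian scatter of check-ins around their area center,
#'   meters.
#' @param seq_len_range Inclusive range of user sequence lengths (default
#'   10-51 check-ins).
#' @param stickiness Probability mass on the designated next state.
#' @param quadrant_mix Marginal probabilities of quadrants I-IV.
#' @param gap_lognormal `c(meanlog, sdlog)` of inter-post gaps in log-hours
#'   (default `log(24)`, 1.2: median one day, tails of days to weeks).
#' @param boundary_noise Probability that a post's emotion readings are
#'   pushed across a quadrant boundary.
#' @param seed RNG seed.
#' @return List of class `synthetic_world`: `areas`, `vertices`, `P`
#'   (transition matrix), `pi` (stationary distribution), `config`.
#' @export
simulate_world <- function(n_areas = 20, n_users = 200, area_centers = NULL,
                           bbox = c(121.0, 30.9, 121.8, 31.5),
                           area_sigma = 150, seq_len_range = c(10, 51),
                           stickiness = 0.8,
                           quadrant_mix = c(0.45, 0.127, 0.139, 0.284),
                           gap_lognormal = c(log(24), 1.2),
                           boundary_noise = 0, seed = NULL) {
  if (abs(sum(quadrant_mix) - 1) > 1e-8 || any(quadrant_mix < 0))
    .stopf("quadrant_mix must be a probability vector over 4 quadrants")
  if (stickiness <= 0 || stickiness > 1) .stopf("stickiness must be in (0, 1]")
  if (seq_len_range[1] < 2 || seq_len_range[2] < seq_len_range[1])
    .stopf("seq_len_range must satisfy 2 <= min <= max")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(area_centers)) {
    ctr <- matrix(NA_real_, n_areas, 2)
    k <- 0L; tries <- 0L
    while (k < n_areas) {
      cand <- c(stats::runif(1, bbox[1], bbox[3]), stats::runif(1, bbox[2], bbox[4]))
      ok <- k == 0L ||
        min(geosphere::distHaversine(matrix(cand, 1), ctr[seq_len(k), , drop = FALSE])) > 2000
      tries <- tries + 1L
      if (ok) { k <- k + 1L; ctr[k, ] <- cand }
      if (tries > 10000L) .stopf("cannot place %d centers 2 km apart in bbox", n_areas)
    }
  } else {
    ctr <- as.matrix(area_centers)
    n_areas <- nrow(ctr)
  }
  areas <- data.frame(area_id = seq_len(n_areas) - 1L, lon = ctr[, 1], lat = ctr[, 2])

  qs <- quadrant_levels()
  vertices <- as.vector(t(outer(areas$area_id, qs, .vertex_key)))
  v_quad <- rep(qs, times = n_areas)
  n_v <- length(vertices)
  base <- quadrant_mix[match(v_quad, qs)] / n_areas   # remainder profile

  # allocate designated-successor quadrants to match the mix as closely as
  # the state count allows (largest-remainder rounding), then shuffle
  raw <- quadrant_mix * n_v
  cnt <- floor(raw)
  rem <- n_v - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  for (attempt in seq_len(100L)) {
    succ_q <- sample(rep.int(1:4, cnt))
    succ_a <- sample.int(n_areas, n_v, replace = TRUE)
    succ <- (succ_a - 1L) * 4L + succ_q
    P <- matrix(0, n_v, n_v, dimnames = list(vertices, vertices))
    for (v in seq_len(n_v)) {
      r <- base
      r[succ[v]] <- 0
      if (stickiness < 1 && sum(r) <= 0)
        .stopf("infeasible quadrant_mix: no mass left for the remainder")
      if (sum(r) > 0) r <- r / sum(r)
      P[v, ] <- (1 - stickiness) * r
      P[v, succ[v]] <- stickiness
    }
    pi <- .stationary(P)
    marg <- as.numeric(rowsum(pi, v_quad)[qs, ])
    if (max(abs(marg - quadrant_mix)) <= 0.05) break
    if (attempt == 100L)
      .stopf("could not match quadrant_mix within 0.05; mix may be infeasible")
  }

  structure(list(areas = areas, vertices = vertices, v_quad = v_quad,
                 P = P, pi = pi,
                 config = list(n_areas = n_areas, n_users = n_users,
                               area_sigma = area_sigma,
                               seq_len_range = seq_len_range,
                               stickiness = stickiness,
                               quadrant_mix = quadrant_mix,
                               gap_lognormal = gap_lognormal,
                               boundary_noise = boundary_noise)),
            class = "synthetic_world")
}

#' Bayes accuracy ceiling of a synthetic world
#'
#' Expected top-1 accuracy of the optimal next-state predictor:
#' `sum_v pi(v) * max_w P(w | v)`. With the default construction this equals
#' the stickiness.
#'
#' @param world A `synthetic_world`.
#' @return Scalar in (0, 1].
#' @export
bayes_rate <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  sum(world$pi * apply(world$P, 1, max))
}

#' Simulate users' check-ins from a synthetic world
#'
#' Each user starts from the stationary distribution, walks the chain for a
#' length drawn uniformly from `seq_len_range`, scatters coordinates
#' Gaussian around the area center, accumulates log-normal inter-post gaps,
#' and emits 1-3 (valence, intensity) readings inside the state's quadrant
#' (pushed across a boundary with probability `boundary_noise`).
#'
#' @param world A `synthetic_world`.
#' @param seed RNG seed.
#' @return List: `checkins` (data.frame as from [read_checkins()]) and
#'   `truth` (data.frame `user_id`, `idx` (row in `checkins`), `area_id`,
#'   `quadrant`).
#' @export
simulate_users <- function(world, seed = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- world$config
  qs <- quadrant_levels()
  deg_lat <- 1 / 111320
  t0 <- 1609459200  # 2021-01-01T00:00:00Z
  rows <- vector("list", cfg$n_users)
  for (u in seq_len(cfg$n_users)) {
    len <- sample(cfg$seq_len_range[1]:cfg$seq_len_range[2], 1L)
    v <- integer(len)
    v[1] <- sample.int(length(world$pi), 1L, prob = world$pi)
    for (i in seq_len(len - 1L))
      v[i + 1L] <- sample.int(ncol(world$P), 1L, prob = world$P[v[i], ])
    a <- (v - 1L) %/% 4L            # 0-based area id
    q <- qs[(v - 1L) %% 4L + 1L]
    lat0 <- world$areas$lat[a + 1L]
    lon0 <- world$areas$lon[a + 1L]
    lat <- lat0 + stats::rnorm(len, 0, cfg$area_sigma) * deg_lat
    lon <- lon0 + stats::rnorm(len, 0, cfg$area_sigma) * deg_lat / cos(lat0 * pi / 180)
    gaps <- stats::rlnorm(len - 1L, cfg$gap_lognormal[1], cfg$gap_lognormal[2]) * 3600
    t <- round(t0 + stats::runif(1, 0, 90 * 86400) + cumsum(c(0, gaps)))
    readings <- lapply(seq_len(len), function(i) {
      n_img <- sample(3L, 1L)
      sg <- .quad_signs[q[i], ]
      m <- cbind(valence = sg[1] * stats::runif(n_img, 0.05, 0.95),
                 intensity = sg[2] * stats::runif(n_img, 0.05, 0.95))
      if (cfg$boundary_noise > 0 && stats::runif(1) < cfg$boundary_noise) {
        ax <- sample(2L, 1L)
        m[, ax] <- -m[, ax]         # push the post across one axis
      }
      m
    })
    rows[[u]] <- data.frame(user_id = sprintf("u%04d", u), t = t,
                            lon = lon, lat = lat, readings = I(readings),
                            area_id = a, quadrant = q)
  }
  all <- do.call(rbind, rows)
  checkins <- all[c("user_id", "t", "lon", "lat", "readings")]
  rownames(checkins) <- NULL
  truth <- data.frame(user_id = all$user_id, idx = seq_len(nrow(all)),
                      area_id = all$area_id, quadrant = all$quadrant)
  list(checkins = checkins, truth = truth)
}

#' Write check-ins to CSV
#'
#' Inverse of [read_checkins()] under the default dialect: columns
#' `time` (ISO-8601 UTC), `y` (lat), `x` (lon), `id`, and up to three
#' valence/intensity pairs `v1 a1 v2 a2 v3 a3` (unused pairs empty).
#'
#' @param checkins Check-in data.frame with a `readings` list-column.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_checkins <- function(checkins, path) {
  nmax <- max(vapply(checkins$readings, nrow, 1L))
  rd <- t(vapply(checkins$readings, function(m) {
    out <- rep(NA_real_, 2L * nmax)
    out[seq_len(2L * nrow(m))] <- as.vector(t(m))
    out
  }, numeric(2L * nmax)))
  colnames(rd) <- paste0(rep(c("v", "a"), nmax), rep(seq_len(nmax), each = 2L))
  df <- data.frame(
    time = format(as.POSIXct(checkins$t, origin = "1970-01-01", tz = "UTC"),
                  "%Y-%m-%dT%H:%M:%SZ"),
    y = checkins$lat, x = checkins$lon, id = checkins$user_id, rd,
    check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
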
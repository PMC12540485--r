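# Density-peak identification of stay areas. Local density uses a Gaussian
# kernel over haversine distances; cluster centers are the points with the
# largest rho * delta, where delta is the distance to the nearest point of
# strictly higher density; remaining points inherit the label of their
# nearest higher-density neighbor. O(n^2) distances, adequate at desk scale.

#' Local density and separation profile of check-in points
#'
#' For each point computes the Gaussian-kernel local density
#' `rho_i = sum_{j != i} exp(-(d_ij / bandwidth)^2)` (haversine `d_ij`,
#' meters), the distance `delta_i` to the nearest point of strictly higher
#' density, and that neighbor's index. Density ties are broken by point
#' index (the lower index counts as denser), which makes the profile
#' deterministic. The globally densest point gets `delta` equal to the
#' maximum pairwise distance and itself as neighbor.
#'
#' @param points Two-column matrix or data.frame of (lon, lat), WGS84 degrees.
#' @param bandwidth Kernel bandwidth in meters (> 0).
#' @return List of class `density_profile`: `rho`, `delta` (meters),
#'   `nearest_higher` (index), plus the inputs.
#' @export
compute_density <- function(points, bandwidth) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) .stopf("points must have two columns (lon, lat)")
  .assert_finite(pts, "coordinates")
  if (!is.finite(bandwidth) || bandwidth <= 0) .stopf("bandwidth must be > 0")
  n <- nrow(pts)
  if (n == 1L) {
    return(structure(list(rho = 0, delta = 0, nearest_higher = 1L,
                          points = pts, bandwidth = bandwidth),
                     class = "density_profile"))
  }
  d <- .haversine_matrix(pts)
  rho <- rowSums(exp(-(d / bandwidth)^2)) - 1  # drop the self term
  # priority: higher rho first, lower index breaks ties
  pr <- order(order(-rho, seq_len(n)))  # pr[i] = rank of point i
  delta <- numeric(n)
  nh <- integer(n)
  for (i in seq_len(n)) {
    higher <- pr < pr[i]
    if (!any(higher)) {            # the densest point
      delta[i] <- max(d[i, ])
      delta[i] <- max(delta[i], max(d))
      nh[i] <- i
    } else {
      di <- d[i, ]
      di[!higher] <- Inf
      nh[i] <- which.min(di)
      delta[i] <- di[nh[i]]
    }
  }
  structure(list(rho = rho, delta = delta, nearest_higher = nh,
                 points = pts, bandwidth = bandwidth),
            class = "density_profile")
}

#' Select cluster centers from a density profile
#'
#' Centers are the `n_centers` points with the largest
#' `gamma_i = rho_i * delta_i`; ties go to the lower index.
#'
#' @param profile A `density_profile` from [compute_density()].
#' @param n_centers Number of centers, between 1 and the number of points.
#' @return Integer vector of point indices (one per center, in selection
#'   order).
#' @export
select_centers <- function(profile, n_centers) {
  stopifnot(inherits(profile, "density_profile"))
  n <- length(profile$rho)
  if (n_centers < 1L || n_centers > n)
    .stopf("n_centers must be in [1, %d], got %s", n, format(n_centers))
  gamma <- profile$rho * profile$delta
  order(-gamma, seq_len(n))[seq_len(n_centers)]
}

#' Assign points to centers by density-connection propagation
#'
#' Points are visited in decreasing density order; each non-center point
#' inherits the label of its nearest higher-density neighbor. Points in the
#' lowest `noise_quantile` of density that are farther than `3 * bandwidth`
#' from any higher-density neighbor are flagged as noise (`NA`).
#'
#' @param profile A `density_profile`.
#' @param centers Center indices from [select_centers()].
#' @param noise_quantile Density quantile below which isolation implies
#'   noise (default 0.01).
#' @return Integer vector of area ids `0..k-1` (position in `centers`),
#'   `NA` for noise.
#' @export
assign_points <- function(profile, centers, noise_quantile = 0.01) {
  stopifnot(inherits(profile, "density_profile"))
  n <- length(profile$rho)
  if (!length(centers) || any(centers < 1L | centers > n))
    .stopf("invalid center indices")
  lab <- rep(NA_integer_, n)
  lab[centers] <- seq_along(centers) - 1L
  ord <- order(-profile$rho, seq_len(n))
  for (i in ord) {
    if (!is.na(lab[i])) next
    up <- profile$nearest_higher[i]
    if (up == i || is.na(lab[up])) {
      # detached root (can happen when the densest point is not a center):
      # fall back to the nearest center by distance
      dc <- geosphere::distHaversine(profile$points[i, , drop = FALSE],
                                     profile$points[centers, , drop = FALSE])
      lab[i] <- lab[centers[which.min(dc)]]
    } else {
      lab[i] <- lab[up]
    }
  }
  if (n > 1L && noise_quantile > 0) {
    thr <- stats::quantile(profile$rho, noise_quantile, names = FALSE)
    noise <- profile$rho <= thr & profile$delta > 3 * profile$bandwidth
    noise[centers] <- FALSE
    lab[noise] <- NA_integer_
  }
  lab
}

#' Identify stay areas from check-ins
#'
#' Runs [compute_density()], [select_centers()] and [assign_points()] and
#' summarises each area by the density-weighted mean of its member
#' coordinates.
#'
#' @param checkins Check-in data.frame (needs `lon`, `lat`), or a
#'   two-column coordinate matrix.
#' @param n_areas Number of stay areas (cluster centers) to extract.
#' @param bandwidth Kernel bandwidth, meters; 500 suits city-scale data.
#' @param noise_quantile Passed to [assign_points()].
#' @return List with `areas` (data.frame `area_id`, `lon`, `lat`,
#'   `member_count`), `assignments` (area id per check-in, `NA` = noise) and
#'   the `profile`.
#' @export
cluster_stay_areas <- function(checkins, n_areas, bandwidth = 500,
                               noise_quantile = 0.01) {
  pts <- if (is.data.frame(checkins) && all(c("lon", "lat") %in% names(checkins)))
    cbind(checkins$lon, checkins$lat) else as.matrix(checkins)
  if (n_areas < 1L) .stopf("n_areas must be >= 1")
  if (nrow(unique(pts)) < n_areas)
    .stopf("only %d distinct points for %d areas", nrow(unique(pts)), n_areas)
  profile <- compute_density(pts, bandwidth)
  centers <- select_centers(profile, n_areas)
  lab <- assign_points(profile, centers, noise_quantile)
  areas <- do.call(rbind, lapply(seq_along(centers) - 1L, function(a) {
    m <- which(!is.na(lab) & lab == a)
    w <- profile$rho[m] + 1e-12
    data.frame(area_id = a,
               lon = sum(pts[m, 1] * w) / sum(w),
               lat = sum(pts[m, 2] * w) / sum(w),
               member_count = length(m))
  }))
  list(areas = areas, assignments = lab, profile = profile)
}
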
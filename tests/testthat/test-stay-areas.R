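test_that("a single point gets the degenerate density profile", {
  pr <- compute_density(cbind(121.3, 30.7), 500)
  expect_equal(pr$rho, 0)
  expect_equal(pr$delta, 0)
  expect_equal(pr$nearest_higher, 1L)
})

test_that("the Gaussian kernel matches a hand evaluation at 1 km", {
  # two points on one meridian: haversine distance is exactly R * dlat
  p1 <- c(121.3, 30.7)
  p2 <- c(121.3, 30.7 + (1000 / 6378137) * 180 / pi)
  pr <- compute_density(rbind(p1, p2), bandwidth = 1000)
  expect_equal(pr$rho, rep(exp(-1), 2), tolerance = 1e-6)
  # equal densities: tie broken by index, so point 1 is the peak
  expect_equal(pr$nearest_higher, c(1L, 1L))
  expect_equal(pr$delta[2], 1000, tolerance = 1e-3)
  expect_equal(pr$delta[1], max(pr$delta), tolerance = 1e-9)
})

test_that("the densest point of a blob carries the maximum pairwise distance", {
  b <- make_blobs(rbind(c(121.3, 30.7)), 100, 200, seed = 3)
  pr <- compute_density(b$points, 500)
  peak <- which.max(pr$rho)
  dmat <- geosphere::distm(b$points, fun = geosphere::distHaversine)
  expect_equal(pr$delta[peak], max(dmat), tolerance = 1e-6)
  expect_equal(pr$nearest_higher[peak], peak)
  expect_true(all(pr$delta[-peak] > 0))
})

test_that("center selection ranks by rho * delta with index tie-break", {
  b <- make_blobs(rbind(c(121.3, 30.7), c(121.5, 30.7)), 30, 100, seed = 4)
  pr <- compute_density(b$points, 500)
  expect_error(select_centers(pr, 0), "n_centers")
  expect_error(select_centers(pr, 999), "n_centers")
  all_ctr <- select_centers(pr, nrow(b$points))
  expect_setequal(all_ctr, seq_len(nrow(b$points)))
  # duplicated coordinates give identical gamma; lower index must win
  dup <- rbind(c(121.3, 30.7), c(121.3, 30.7), c(121.4, 30.8))
  prd <- compute_density(dup, 500)
  g <- prd$rho * prd$delta
  expect_identical(select_centers(prd, 1L),
                   which(g == max(g))[1])
})

test_that("three well-separated blobs are recovered almost perfectly", {
  ctr <- rbind(c(121.30, 30.70), c(121.30, 30.79), c(121.42, 30.70))  # >= 5 km apart
  b <- make_blobs(ctr, 200, 100, seed = 7)
  res <- cluster_stay_areas(b$points, n_areas = 3, bandwidth = 500)
  expect_gte(ari(ifelse(is.na(res$assignments), -1, res$assignments), b$labels), 0.95)
  # one center per blob
  pr <- res$profile
  centers <- select_centers(pr, 3)
  expect_setequal(unique(b$labels[centers]), 1:3)
  # conservation: every point assigned or noise
  expect_equal(sum(res$areas$member_count) + sum(is.na(res$assignments)),
               nrow(b$points))
})

test_that("the partition is invariant to input order", {
  ctr <- rbind(c(121.30, 30.70), c(121.30, 30.79), c(121.42, 30.70))
  b <- make_blobs(ctr, 60, 100, seed = 8)
  res1 <- cluster_stay_areas(b$points, 3, 500)
  set.seed(9)
  perm <- sample(nrow(b$points))
  res2 <- cluster_stay_areas(b$points[perm, ], 3, 500)
  l1 <- ifelse(is.na(res1$assignments), -1, res1$assignments)[perm]
  l2 <- ifelse(is.na(res2$assignments), -1, res2$assignments)
  expect_equal(ari(l1, l2), 1.0)
})

test_that("an isolated far-away point is classified as noise", {
  b <- make_blobs(rbind(c(121.30, 30.70)), 120, 100, seed = 10)
  far <- geosphere::destPoint(c(121.30, 30.70), b = 45, d = 50000)
  pts <- rbind(b$points, far)
  res <- cluster_stay_areas(pts, 1, 500, noise_quantile = 0.01)
  expect_true(is.na(res$assignments[nrow(pts)]))
  expect_true(all(!is.na(res$assignments[-nrow(pts)])))
})

test_that("label propagation matches a brute-force oracle on small inputs", {
  ctr <- rbind(c(121.30, 30.70), c(121.33, 30.72))
  b <- make_blobs(ctr, 80, 150, seed = 11)
  pr <- compute_density(b$points, 400)
  centers <- select_centers(pr, 2)
  got <- assign_points(pr, centers, noise_quantile = 0)
  # oracle: sort by density (ties by index), propagate labels downward
  n <- length(pr$rho)
  lab <- rep(NA_integer_, n)
  lab[centers] <- seq_along(centers) - 1L
  for (i in order(-pr$rho, seq_len(n)))
    if (is.na(lab[i])) lab[i] <- lab[pr$nearest_higher[i]]
  expect_identical(got, lab)
})

test_that("area count preconditions hold", {
  b <- make_blobs(rbind(c(121.3, 30.7)), 30, 100, seed = 12)
  expect_error(cluster_stay_areas(b$points, 0), "n_areas")
  expect_error(cluster_stay_areas(b$points[c(1, 1), ], 3), "distinct")
  res <- cluster_stay_areas(b$points, 1, 500)
  expect_true(all(res$assignments[!is.na(res$assignments)] == 0L))
})
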
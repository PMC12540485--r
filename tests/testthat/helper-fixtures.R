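# Shared fixture builders (all fixtures generated in code, seeded).

# Gaussian blobs of lon/lat points around given centers (sigma in meters).
make_blobs <- function(centers, n_per, sigma_m, seed = 1) {
  set.seed(seed)
  deg <- 1 / 111320
  pts <- lapply(seq_len(nrow(centers)), function(k) {
    lat <- centers[k, 2] + rnorm(n_per, 0, sigma_m) * deg
    lon <- centers[k, 1] + rnorm(n_per, 0, sigma_m) * deg / cos(centers[k, 2] * pi / 180)
    cbind(lon, lat)
  })
  list(points = do.call(rbind, pts),
       labels = rep(seq_len(nrow(centers)), each = n_per))
}

# A small labelled check-in set wired through the real generator.
make_tiny_world_data <- function(n_areas = 4, n_users = 15,
                                 seq_len_range = c(6, 10), seed = 5) {
  w <- simulate_world(n_areas = n_areas, n_users = n_users,
                      seq_len_range = seq_len_range, seed = seed)
  sim <- simulate_users(w, seed = seed + 1)
  list(world = w, checkins = label_checkins(sim$checkins), truth = sim$truth)
}

# Write a CSV of check-in rows from a character vector body (default header).
write_checkin_csv <- function(lines, header = "time,y,x,id,v1,a1") {
  f <- tempfile(fileext = ".csv")
  writeLines(c(header, lines), f)
  f
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
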
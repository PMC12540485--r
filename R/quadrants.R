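#' Validate a single (valence, intensity) emotion reading
#'
#' Both coordinates must lie in `[-1, 1]`; valence is the pleasantness axis,
#' intensity the activation axis of the Russell circumplex.
#'
#' @param x Valence.
#' @param y Intensity.
#' @return Named numeric vector `c(x =, y =)`.
#' @export
validate_reading <- function(x, y) {
  if (!is.finite(x) || abs(x) > 1) .stopf("valence %s outside [-1, 1]", format(x))
  if (!is.finite(y) || abs(y) > 1) .stopf("intensity %s outside [-1, 1]", format(y))
  c(x = x, y = y)
}

#' Aggregate per-image emotion readings into a post-level emotion
#'
#' The post emotion is the raw componentwise sum of its image readings
#' (many-image posts therefore carry proportionally more weight; set
#' `mean = TRUE` for an average instead).
#'
#' @param readings Two-column matrix (valence, intensity), one row per image.
#' @param mean Average instead of sum (off by default).
#' @return Named vector `c(x =, y =, n =)` with the aggregated coordinates
#'   and the number of images.
#' @export
aggregate_post <- function(readings, mean = FALSE) {
  readings <- rbind(readings)
  if (nrow(readings) == 0L) .stopf("cannot aggregate an empty reading list")
  if (any(!is.finite(readings)) || any(abs(readings) > 1))
    .stopf("emotion readings must be finite and within [-1, 1]")
  s <- colSums(readings)
  if (mean) s <- s / nrow(readings)
  c(x = unname(s[1]), y = unname(s[2]), n = nrow(readings))
}

#' Map aggregated emotions to Russell quadrants
#'
#' Quadrant I is high valence/high intensity, II low/high, III low/low,
#' IV high/low. Values exactly on an axis count as "low" on that axis, so
#' the four cases partition the plane: `x>0,y>0 -> I`; `x<=0,y>0 -> II`;
#' `x<=0,y<=0 -> III`; `x>0,y<=0 -> IV`.
#'
#' @param x Valence (vectorized).
#' @param y Intensity (vectorized, recycled against `x`).
#' @return Character vector of quadrant labels (see [quadrant_levels()]).
#' @export
quadrant_of <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    .stopf("non-finite emotion coordinates")
  q <- ifelse(x > 0, ifelse(y > 0, 1L, 4L), ifelse(y > 0, 2L, 3L))
  quadrant_levels()[q]
}

#' Label check-ins with post-level emotion and quadrant
#'
#' Applies [aggregate_post()] and [quadrant_of()] to every check-in.
#'
#' @param checkins Check-in data.frame from [read_checkins()].
#' @param mean Passed to [aggregate_post()].
#' @return `checkins` with added columns `x`, `y` (aggregated emotion) and
#'   `quadrant`.
#' @export
label_checkins <- function(checkins, mean = FALSE) {
  agg <- t(vapply(checkins$readings, aggregate_post, numeric(3), mean = mean))
  checkins$x <- agg[, "x"]
  checkins$y <- agg[, "y"]
  checkins$quadrant <- quadrant_of(agg[, "x"], agg[, "y"])
  checkins
}
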
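#' Quadrant labels of the Russell circumplex
#'
#' The four emotional quadrants in order: `"I"` (high valence, high
#' intensity), `"II"` (low valence, high intensity), `"III"` (low valence,
#' low intensity), `"IV"` (high valence, low intensity).
#'
#' @return Character vector of length four.
#' @export
quadrant_levels <- function() c("I", "II", "III", "IV")

# Parse timestamps in either ISO-8601 or the legacy microblog dialect
# "Fri Jan 01 05:09:23 +0800 2021". Returns epoch seconds (UTC) or NA.
.parse_time <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  old <- Sys.getlocale("LC_TIME")
  on.exit(try(Sys.setlocale("LC_TIME", old), silent = TRUE), add = TRUE)
  try(Sys.setlocale("LC_TIME", "C"), silent = TRUE)

  legacy <- grepl("^[A-Za-z]{3} [A-Za-z]{3} ", x)
  if (any(legacy)) {
    p <- strptime(gsub("\\+ ", "+", x[legacy]), "%a %b %d %H:%M:%S %z %Y", tz = "UTC")
    out[legacy] <- as.numeric(p)
  }
  iso <- !legacy
  if (any(iso)) {
    y <- x[iso]
    y <- sub("T", " ", y, fixed = TRUE)
    y <- sub("Z$", " +0000", y)
    # "+08:00" -> "+0800"
    y <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", y)
    has_tz <- grepl("[+-]\\d{4}$", y)
    v <- rep(NA_real_, length(y))
    if (any(has_tz))
      v[has_tz] <- as.numeric(strptime(y[has_tz], "%Y-%m-%d %H:%M:%S %z", tz = "UTC"))
    if (any(!has_tz))
      v[!has_tz] <- as.numeric(as.POSIXct(y[!has_tz], tz = "UTC",
                                          format = "%Y-%m-%d %H:%M:%S"))
    out[iso] <- v
  }
  out
}

#' Read a check-in table from CSV
#'
#' Reads geotagged posts with one or more pre-extracted (valence, intensity)
#' emotion readings per post. Timestamps may be ISO-8601 (`2021-01-01T05:09:23Z`,
#' with or without a numeric offset) or the microblog export dialect
#' `"Fri Jan 01 05:09:23 +0800 2021"`; both resolve to the same epoch second.
#'
#' @param path CSV file with a header row.
#' @param dialect Named list mapping roles to column names:
#'   `time`, `lat`, `lon`, `user`, and optionally `readings`, a character
#'   vector of alternating valence/intensity column names. When `readings`
#'   is `NULL`, all remaining columns are paired in file order.
#' @return A data.frame with columns `user_id`, `t` (epoch seconds, UTC),
#'   `lon`, `lat` and a list-column `readings` of two-column
#'   (valence, intensity) matrices; rows keep file order.
#' @export
read_checkins <- function(path,
                          dialect = list(time = "time", lat = "y",
                                         lon = "x", user = "id")) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time", "lat", "lon", "user")
  for (k in need) {
    if (is.null(dialect[[k]]) || !dialect[[k]] %in% names(raw))
      .stopf("dialect column '%s' (%s) not found in %s", k,
             dialect[[k]] %||% "<missing>", path)
  }
  if (nrow(raw) == 0L) {
    warning("empty check-in file: ", path)
    return(data.frame(user_id = character(), t = numeric(),
                      lon = numeric(), lat = numeric(),
                      readings = I(list())))
  }
  t <- .parse_time(raw[[dialect$time]])
  bad <- which(!is.finite(t))
  if (length(bad))
    .stopf("unparseable timestamp at data row %d: '%s'", bad[1],
           raw[[dialect$time]][bad[1]])
  lat <- as.numeric(raw[[dialect$lat]])
  lon <- as.numeric(raw[[dialect$lon]])
  bad <- which(!is.finite(lat) | lat < -90 | lat > 90)
  if (length(bad)) .stopf("latitude out of [-90, 90] at data row %d", bad[1])
  bad <- which(!is.finite(lon) | lon < -180 | lon > 180)
  if (length(bad)) .stopf("longitude out of [-180, 180] at data row %d", bad[1])

  rcols <- dialect$readings
  if (is.null(rcols)) {
    rcols <- setdiff(names(raw), unlist(dialect[need]))
  }
  if (length(rcols) == 0L || length(rcols) %% 2L != 0L)
    .stopf("need an even, non-empty set of reading columns; got: %s",
           paste(rcols, collapse = ", "))
  vals <- as.matrix(raw[rcols])
  storage.mode(vals) <- "double"
  readings <- lapply(seq_len(nrow(vals)), function(i) {
    m <- matrix(vals[i, ], ncol = 2L, byrow = TRUE,
                dimnames = list(NULL, c("valence", "intensity")))
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) == 0L)
      .stopf("no emotion reading at data row %d", i)
    if (any(abs(m) > 1))
      .stopf("emotion reading out of [-1, 1] at data row %d", i)
    m
  })
  data.frame(user_id = as.character(raw[[dialect$user]]), t = t,
             lon = lon, lat = lat, readings = I(readings))
}

#' Write stay areas as GeoJSON
#'
#' One `Point` feature per stay-area center with `area_id` and
#' `member_count` properties (RFC 7946 FeatureCollection).
#'
#' @param areas Data.frame with columns `area_id`, `lon`, `lat`,
#'   `member_count` (as returned by [cluster_stay_areas()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stay_areas <- function(areas, path) {
  if (is.null(areas) || nrow(areas) == 0L) .stopf("no stay areas to write")
  features <- lapply(seq_len(nrow(areas)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(areas$lon[i], areas$lat[i])),
         properties = list(area_id = areas$area_id[i],
                           member_count = areas$member_count[i]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read stay areas from GeoJSON
#'
#' Inverse of [write_stay_areas()].
#'
#' @param path GeoJSON file.
#' @return Data.frame with `area_id`, `lon`, `lat`, `member_count`.
#' @export
read_stay_areas <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) .stopf("not a FeatureCollection: %s", path)
  rows <- lapply(fc$features, function(f) {
    data.frame(area_id = as.integer(f$properties$area_id),
               lon = as.numeric(f$geometry$coordinates[[1]]),
               lat = as.numeric(f$geometry$coordinates[[2]]),
               member_count = as.integer(f$properties$member_count))
  })
  do.call(rbind, rows)
}

#' Write / read the emotional interaction graph as a TSV edge list
#'
#' Columns: `src_area src_quadrant dst_area dst_quadrant weight`.
#' Reading recomputes per-vertex weighted out-degrees; a round trip is the
#' identity up to weight round-off below 1e-9.
#'
#' @param graph An `emotion_graph` (see [build_graph()]).
#' @param path File path.
#' @return `write_edge_list`: `path` invisibly; `read_edge_list`: an
#'   `emotion_graph`.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "emotion_graph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) .stopf("edge list has no data rows: %s", path)
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5L))
    .stopf("malformed edge-list line %d (expected 5 fields, got %d)",
           which(nf != 5L)[1] + 1L, nf[nf != 5L][1])
  m <- do.call(rbind, parts)
  edges <- data.frame(src_area = as.integer(m[, 1]), src_quadrant = m[, 2],
                      dst_area = as.integer(m[, 3]), dst_quadrant = m[, 4],
                      weight = as.numeric(m[, 5]))
  if (any(!edges$src_quadrant %in% quadrant_levels()) ||
      any(!edges$dst_quadrant %in% quadrant_levels()))
    .stopf("unknown quadrant label in edge list %s", path)
  bad <- which(!is.finite(edges$weight) | edges$weight <= 0)
  if (length(bad)) .stopf("non-positive or non-finite weight at line %d", bad[1] + 1L)
  .make_graph(edges)
}

#' Write / read an embedding table as TSV
#'
#' Columns: `area quadrant v1 ... vd`, one row per graph vertex.
#'
#' @param table Numeric matrix with rownames `"<area>:<quadrant>"`
#'   (as returned by [line_embed()]).
#' @param path File path.
#' @return `write_embedding`: `path` invisibly; `read_embedding`: the matrix.
#' @export
write_embedding <- function(table, path) {
  stopifnot(is.matrix(table), !is.null(rownames(table)))
  key <- do.call(rbind, strsplit(rownames(table), ":", fixed = TRUE))
  df <- data.frame(area = as.integer(key[, 1]), quadrant = key[, 2],
                   table, check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("v", seq_len(ncol(table)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(m) <- list(paste0(df$area, ":", df$quadrant), NULL)
  .assert_finite(m, "embedding table")
  m
}
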
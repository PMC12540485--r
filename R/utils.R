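# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with -Inf support (masked entries).
.softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e[is.na(e)] <- 0
  e / rowSums(e)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_finite <- function(x, what) {
  if (!all(is.finite(x))) .stopf("non-finite value in %s", what)
  invisible(x)
}

# Pairwise haversine distances in meters, chunked to bound memory on large n.
.haversine_matrix <- function(lonlat, chunk = 2000L) {
  lonlat <- as.matrix(lonlat)
  n <- nrow(lonlat)
  out <- matrix(0, n, n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    out[i0:i1, ] <- geosphere::distm(lonlat[i0:i1, , drop = FALSE], lonlat,
                                     fun = geosphere::distHaversine)
  }
  out
}

# Deterministic per-stage seed derivation from one pipeline seed (FNV-1a over
# the stage name, folded with a splitmix-style mix, kept below 2^31).
.derive_seed <- function(seed, stage) {
  h <- 2166136261
  for (ch in utf8ToInt(stage)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  as.integer((h + seed * 2654435761) %% 2147483647)
}

# Small FNV-1a hex hash of a string (used to stamp pipeline configs).
.hash_string <- function(s) {
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
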
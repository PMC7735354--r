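# Internal numerical helpers shared across modules.

# Earth radius used for all geodesic computations (km). Spherical model keeps
# errors well below 0.5% at foraging-trip scales.
EARTH_RADIUS_KM <- 6371

# Great-circle distance in km between successive or paired points.
# lon/lat in decimal degrees.
haversineKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# Centered moving mean with the window shrinking at the edges, so the first
# and last samples average over half a window. Vectorized via cumulative sums.
movingMean <- function(x, width) {
  n <- length(x)
  width <- as.integer(width)
  if (width <= 1) return(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Fold a sample vector into complete per-second columns (drops a trailing
# partial second).
perSecondMatrix <- function(x, rateHz) {
  ns <- floor(length(x) / rateHz)
  matrix(x[seq_len(ns * rateHz)], nrow = rateHz)
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used only to
# fingerprint configurations in run manifests.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keeps h a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, split to stay
    # within exact double-precision integer range
    hi <- ((h %/% 65536) * 16777619) %% 65536
    lo <- (h %% 65536) * 16777619
    h <- (hi * 65536 + lo) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Local solar time offset (hours) from UTC at a given longitude.
solarOffsetH <- function(lon) lon / 15

`%||%` <- function(a, b) if (is.null(a)) b else a
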
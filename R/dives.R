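#' Convert pressure to depth
#'
#' \eqn{D = 0.01 (P_m - P_a)}: depth in metres from measured pressure and
#' the atmospheric baseline, both in mBar. Negative values are permitted
#' before zero-offset correction.
#'
#' @param pm measured pressure series (mBar).
#' @param pa atmospheric baseline pressure (mBar), > 0.
#' @return numeric depth series (m).
#' @export
pressureToDepth <- function(pm, pa) {
  if (pa <= 0) stop("atmospheric pressure must be positive")
  0.01 * (pm - pa)
}

#' Zero-offset (surface drift) correction
#'
#' Re-anchors the surface reading to zero by subtracting a rolling
#' lower-quantile baseline (default: 2% quantile over a centered 10 min
#' window). A window longer than the series degrades to a single global
#' baseline.
#'
#' @param depth depth series at 1 Hz (m).
#' @param windowS rolling window (s).
#' @param q lower quantile used as the surface baseline.
#' @return corrected depth series (m).
#' @export
correctSurfaceDrift <- function(depth, windowS = 600, q = 0.02) {
  n <- length(depth)
  if (n == 0) return(depth)
  if (windowS >= n)
    return(depth - stats::quantile(depth, q, names = FALSE))
  base <- zoo::rollapply(zoo::zoo(depth), width = windowS,
                         FUN = stats::quantile, probs = q, names = FALSE,
                         align = "center", partial = TRUE)
  depth - as.numeric(base)
}

#' Detect dives in a corrected depth series
#'
#' A dive is a maximal submerged excursion (depth > 0) bounded by surface
#' crossings whose maximum depth strictly exceeds \code{thresholdM}
#' (default 0.55 m, one body length — shallower submergences are treated as
#' sensor noise). Descent duration runs from the excursion start to the
#' deepest sample; descent rate is max depth over descent duration.
#'
#' @param depth corrected depth series at \code{rateHz} (m).
#' @param thresholdM minimum depth for a dive (m), strict inequality.
#' @param rateHz sampling rate of the depth series (Hz).
#' @param surfaceEpsM wet threshold (m) above which a sample counts as
#'   submerged; keeps residual surface noise (sensor resolution is 5 mBar =
#'   0.05 m) from bridging or extending excursions.
#' @return data.frame, one row per dive: \code{start_s}, \code{end_s},
#'   \code{duration_s}, \code{max_depth_m}, \code{descent_duration_s},
#'   \code{descent_rate_ms}, \code{source} (= \code{"pressure"}).
#' @export
detectDives <- function(depth, thresholdM = 0.55, rateHz = 1,
                        surfaceEpsM = 0.1) {
  sub <- depth > surfaceEpsM
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), max_depth_m = numeric(),
                      descent_duration_s = numeric(),
                      descent_rate_ms = numeric(), source = character())
  if (!any(sub)) return(empty)
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- depth[i0:i1]
    mx <- max(seg)
    if (mx <= thresholdM) next
    apex <- which.max(seg)
    # time origin: the last surface sample before submergence
    startS <- (i0 - 2) / rateHz
    descent <- (i0 - 1 + apex - 1) / rateHz - startS
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = max(startS, 0), end_s = i1 / rateHz,
      duration_s = i1 / rateHz - max(startS, 0),
      max_depth_m = mx, descent_duration_s = descent,
      descent_rate_ms = mx / descent, source = "pressure")
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fleet descent rate
#'
#' Common descent rate across dives: the slope of the zero-intercept least
#' squares fit of maximum depth on descent duration. Used to estimate dive
#' depth on loggers without a pressure sensor.
#'
#' @param dives data.frame from [detectDives()] (>= 3 dives).
#' @return list with \code{rateMs} (fleet slope) and \code{perDiveRates}.
#' @export
fleetDescentRate <- function(dives) {
  if (nrow(dives) < 3) stop("need at least 3 dives to estimate a fleet rate")
  t <- dives$descent_duration_s
  d <- dives$max_depth_m
  list(rateMs = sum(d * t) / sum(t^2), perDiveRates = d / t)
}

#' Estimate dive depth from dive duration
#'
#' For V-shaped dives with equal descent and ascent rates, the descent
#' occupies half the dive, so \eqn{depth = rate \times duration / 2}.
#'
#' @param durationS dive duration (s), >= 0.
#' @param rateMs descent rate (m/s), > 0.
#' @return estimated depth (m).
#' @export
depthFromDuration <- function(durationS, rateMs = 0.84) {
  if (any(durationS < 0)) stop("duration must be non-negative")
  if (rateMs <= 0) stop("descent rate must be positive")
  rateMs * durationS / 2
}

#' Cross-validate acceleration-detected foraging against pressure dives
#'
#' Fraction of pressure-detected dives that an acceleration-derived foraging
#' event overlaps within a +/- \code{matchWindowS} tolerance, as a
#' percentage. This is the yardstick for applying the acceleration-only
#' classifier to birds carrying no pressure sensor.
#'
#' @param accelEvents data.frame with \code{start_s}, \code{end_s}.
#' @param pressureDives data.frame with \code{start_s}, \code{end_s}.
#' @param matchWindowS match tolerance (s).
#' @return percentage in [0, 100], or NA when there are no pressure dives.
#' @export
validateDetection <- function(accelEvents, pressureDives, matchWindowS = 2) {
  if (!nrow(pressureDives)) return(NA_real_)
  if (!nrow(accelEvents)) return(0)
  hit <- vapply(seq_len(nrow(pressureDives)), function(i) {
    any(accelEvents$start_s <= pressureDives$end_s[i] + matchWindowS &
        accelEvents$end_s >= pressureDives$start_s[i] - matchWindowS)
  }, logical(1))
  100 * sum(hit) / length(hit)
}

#' Full pressure-channel dive analysis
#'
#' Convenience wrapper: depth conversion, zero-offset correction and dive
#' detection for an \linkS4class{AccelTrace} carrying pressure.
#'
#' @param trace an \linkS4class{AccelTrace} with a pressure channel.
#' @param cfg an [analysisConfig()].
#' @param pa atmospheric baseline (mBar); defaults to the series' 2% quantile.
#' @return list with \code{depth} (corrected series) and \code{dives}.
#' @export
analyzePressure <- function(trace, cfg = analysisConfig(), pa = NULL) {
  pm <- pressureSeries(trace)
  if (is.null(pm)) stop("trace has no pressure channel")
  if (is.null(pa)) pa <- stats::quantile(pm, 0.02, names = FALSE)
  depth <- correctSurfaceDrift(pressureToDepth(pm, pa),
                               windowS = cfg$driftWindowS,
                               q = cfg$driftQuantile)
  dives <- detectDives(depth, thresholdM = cfg$diveThresholdM,
                       rateHz = trace@pressureRateHz)
  list(depth = depth, dives = dives)
}
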
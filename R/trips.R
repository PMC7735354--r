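#' Speed-filter a GPS track
#'
#' Forward pass removing implausible fixes: starting from the first fix
#' (always retained), a fix is dropped when the great-circle speed from the
#' last retained fix exceeds \code{vmaxMs}. The filter is idempotent.
#'
#' @param track a \linkS4class{GpsTrack}.
#' @param vmaxMs maximum plausible speed (m/s), default 25.
#' @return The filtered \linkS4class{GpsTrack}.
#' @export
filterSpeed <- function(track, vmaxMs = 25) {
  f <- fixes(track)
  n <- nrow(f)
  if (n <= 1) return(track)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1
  tnum <- as.numeric(f$time)
  for (i in 2:n) {
    dt <- tnum[i] - tnum[last]
    dKm <- haversineKm(f$lon[last], f$lat[last], f$lon[i], f$lat[i])
    if (dKm * 1000 / dt <= vmaxMs) {
      keep[i] <- TRUE
      last <- i
    }
  }
  gpsTrack(f$time[keep], f$lat[keep], f$lon[keep], deploymentId(track))
}

#' Segment a track into central-place foraging trips
#'
#' A trip is a maximal run of fixes farther than \code{cfg$colonyRadiusKm}
#' from the colony, bracketed by the nearest fixes inside the radius (when
#' they exist). Runs of fewer than 3 at-sea fixes are discarded. On-land and
#' colony-attendance fixes are thereby excluded from all trip statistics.
#'
#' @param track a \linkS4class{GpsTrack}.
#' @param cfg an [analysisConfig()] providing \code{colony} and
#'   \code{colonyRadiusKm}.
#' @return list of \linkS4class{Trip} objects (possibly empty).
#' @export
segmentTrips <- function(track, cfg = analysisConfig()) {
  f <- fixes(track)
  if (!nrow(f)) return(list())
  dKm <- haversineKm(cfg$colony[2], cfg$colony[1], f$lon, f$lat)
  outside <- dKm > cfg$colonyRadiusKm
  if (!any(outside)) {
    message("track never leaves the colony radius; no trips")
    return(list())
  }
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trips <- list()
  for (k in which(r$values)) {
    if (r$lengths[k] < 3) next
    i0 <- max(starts[k] - 1L, 1L)
    i1 <- min(ends[k] + 1L, nrow(f))
    trips[[length(trips) + 1L]] <-
      new("Trip", fixes = f[i0:i1, , drop = FALSE],
          deploymentId = deploymentId(track),
          tripId = length(trips) + 1L)
  }
  trips
}

#' Trip metrics
#'
#' Duration, maximum great-circle distance from the colony, total horizontal
#' distance (sum of consecutive haversine legs) and mean horizontal speed.
#'
#' @param trip a \linkS4class{Trip}.
#' @param colony c(lat, lon) of the colony.
#' @return data.frame with one row: \code{deployment_id}, \code{trip_id},
#'   \code{duration_h}, \code{max_distance_km}, \code{total_distance_km},
#'   \code{mean_speed_kmh}, \code{n_fixes}.
#' @export
tripMetrics <- function(trip, colony = c(-42.146, 171.341)) {
  f <- fixes(trip)
  n <- nrow(f)
  dur <- as.numeric(difftime(f$time[n], f$time[1], units = "hours"))
  if (dur <= 0) stop("zero-duration trip")
  legs <- haversineKm(f$lon[-n], f$lat[-n], f$lon[-1], f$lat[-1])
  total <- sum(legs)
  maxD <- max(haversineKm(colony[2], colony[1], f$lon, f$lat))
  data.frame(deployment_id = trip@deploymentId, trip_id = trip@tripId,
             duration_h = dur, max_distance_km = maxD,
             total_distance_km = total, mean_speed_kmh = total / dur,
             n_fixes = n)
}

#' Linearly interpolate a trip to a dense location sequence
#'
#' Linear interpolation of latitude and longitude between consecutive fixes
#' at a fixed interval; endpoints are preserved.
#'
#' @param trip a \linkS4class{Trip} or \linkS4class{GpsTrack} with >= 2 fixes.
#' @param intervalS interpolation step (s), default 1.
#' @return data.frame with \code{time}, \code{lat}, \code{lon} and
#'   \code{elapsed_s} (seconds since the first fix).
#' @export
interpolateTrip <- function(trip, intervalS = 1) {
  f <- fixes(trip)
  if (nrow(f) < 2) stop("need at least 2 fixes to interpolate")
  t0 <- as.numeric(f$time[1])
  el <- as.numeric(f$time) - t0
  grid <- seq(0, el[length(el)], by = intervalS)
  data.frame(
    time = f$time[1] + grid,
    lat = stats::approx(el, f$lat, xout = grid)$y,
    lon = stats::approx(el, f$lon, xout = grid)$y,
    elapsed_s = grid)
}

#' Convex-polygon home-range area
#'
#' Area of the convex hull of a set of locations (maximum convex polygon),
#' computed on a sphere of radius 6371 km. Duplicate points are dropped
#' before hull construction; fewer than 3 distinct non-collinear points is
#' an error.
#'
#' @param locations data.frame with \code{lat} and \code{lon} columns.
#' @return area in km^2.
#' @export
mcpArea <- function(locations) {
  pts <- unique(locations[, c("lon", "lat")])
  if (nrow(pts) < 3) stop("need at least 3 distinct points")
  h <- grDevices::chull(pts$lon, pts$lat)
  if (length(h) < 3) stop("points are collinear; hull has no area")
  hull <- pts[h, ]
  area <- geosphere::areaPolygon(as.matrix(hull),
                                 a = EARTH_RADIUS_KM * 1000, f = 0) / 1e6
  if (!is.finite(area) || area <= 0)
    stop("points are collinear; hull has no area")
  area
}

#' Bimodality coefficient
#'
#' \eqn{BC = (g^2 + 1) / (k + 3(n-1)^2 / ((n-2)(n-3)))} with \eqn{g} the
#' sample skewness and \eqn{k} the sample excess kurtosis, both with the
#' SAS-style small-sample bias corrections (type 2 of
#' \code{e1071::skewness()}). Values above 5/9 (~0.555) suggest more than
#' one mode: a uniform distribution sits exactly at the 5/9 benchmark and a
#' normal at 1/3.
#'
#' @param x numeric sample (n >= 4), e.g. trip durations in hours.
#' @return the bimodality coefficient, in (0, 1].
#' @export
bimodalityCoefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("bimodality coefficient needs n >= 4")
  if (stats::sd(x) == 0) stop("bimodality coefficient undefined for constant data")
  g <- e1071::skewness(x, type = 2)
  k <- e1071::kurtosis(x, type = 2)
  (g^2 + 1) / (k + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Estimate trip-duration modes by normal mixture
#'
#' Fits 1- and 2-component normal mixtures by maximum likelihood (EM, via
#' \pkg{mclust}) and selects the number of components by BIC; component means
#' are reported as modes. A degenerate 2-component fit (a component with
#' near-zero variance or weight) falls back to the single-component fit with
#' a message.
#'
#' @param x numeric sample, n >= 10 (constant vectors return their value as
#'   the single mode).
#' @return data.frame with columns \code{location} and \code{weight}, sorted
#'   by location.
#' @export
estimateModes <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("mode estimation needs n >= 10")
  if (stats::sd(x) == 0)
    return(data.frame(location = x[1], weight = 1))
  fit <- mclustFit(x, G = 1:2)
  mu <- as.numeric(fit$parameters$mean)
  w <- as.numeric(fit$parameters$pro)
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(mu) > 1 &&
      (any(sig < 1e-8 * stats::sd(x)) || any(w < 1e-3))) {
    message("degenerate mixture component; falling back to one mode")
    fit <- mclustFit(x, G = 1)
    mu <- as.numeric(fit$parameters$mean)
    w <- 1
  }
  o <- order(mu)
  data.frame(location = mu[o], weight = w[o])
}

# Mclust resolves its helper functions (mclustBIC etc.) in the caller's
# search path, so evaluate the call inside the mclust namespace instead of
# requiring the package to be attached.
mclustFit <- function(x, G) {
  eval(quote(Mclust(data, G = G, modelNames = c("E", "V"), verbose = FALSE)),
       list(data = x, G = G), asNamespace("mclust"))
}

#' Trip-duration modality summary
#'
#' Convenience wrapper combining [bimodalityCoefficient()] and
#' [estimateModes()].
#'
#' @param durationsH trip durations in hours.
#' @return list with \code{bc}, \code{flagBimodal} (BC > 5/9) and
#'   \code{modes}.
#' @export
modalityStats <- function(durationsH) {
  bc <- bimodalityCoefficient(durationsH)
  list(bc = bc, flagBimodal = bc > 5 / 9, modes = estimateModes(durationsH))
}
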
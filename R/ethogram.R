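#' Static/dynamic decomposition of tri-axial acceleration
#'
#' Separates the gravitational (static) component from body movement
#' (dynamic) on each axis with a centered running mean over
#' \code{windowS} seconds (window shrinking at the edges). By construction
#' static + dynamic reconstructs the raw signal exactly, per sample.
#'
#' @param trace an \linkS4class{AccelTrace}.
#' @param windowS running-mean window (s); \code{rateHz * windowS} must be
#'   at least 3.
#' @return list of class \code{"staticDynamic"} with elements \code{static}
#'   and \code{dynamic} (each a list of \code{ax}, \code{ay}, \code{az}) and
#'   \code{rateHz}.
#' @export
decomposeAcceleration <- function(trace, windowS = 1) {
  rate <- rateHz(trace)
  w <- round(rate * windowS)
  if (w < 3) stop("window too short: rateHz * windowS must be >= 3")
  if (length(trace@ax) < w) stop("trace shorter than the decomposition window")
  st <- list(ax = movingMean(trace@ax, w),
             ay = movingMean(trace@ay, w),
             az = movingMean(trace@az, w))
  dyn <- list(ax = trace@ax - st$ax, ay = trace@ay - st$ay,
              az = trace@az - st$az)
  structure(list(static = st, dynamic = dyn, rateHz = rate),
            class = "staticDynamic")
}

#' Body pitch from static acceleration
#'
#' \eqn{pitch = atan(Ax / sqrt(Ay^2 + Az^2)) \times 180 / \pi} on the static
#' components: the angle of the surge axis against horizontal. Strongly
#' negative pitch marks head-down prey seizing. When the sway and heave
#' statics are both zero the pitch is +/-90 by the sign of the surge; an
#' all-zero static vector yields NA.
#'
#' @param sd a \code{"staticDynamic"} decomposition.
#' @return numeric vector of pitch in degrees, one per sample, in [-90, 90].
#' @export
bodyPitch <- function(sd) {
  ax <- sd$static$ax
  denom <- sqrt(sd$static$ay^2 + sd$static$az^2)
  p <- atan2(ax, denom) * 180 / pi
  p[denom == 0 & ax == 0] <- NA_real_
  p
}

#' Vectorial dynamic body acceleration (VeDBA)
#'
#' Euclidean norm of the three dynamic axes per sample, a proxy of
#' whole-body movement cost.
#'
#' @param sd a \code{"staticDynamic"} decomposition.
#' @return numeric vector in g, one value per sample.
#' @seealso [perSecondMeans()] to aggregate per second.
#' @export
vedba <- function(sd) {
  sqrt(sd$dynamic$ax^2 + sd$dynamic$ay^2 + sd$dynamic$az^2)
}

#' Aggregate a sample series into per-second means
#'
#' @param x numeric vector sampled at \code{rateHz}.
#' @param rateHz sampling rate (Hz).
#' @return numeric vector, one mean per complete second.
#' @export
perSecondMeans <- function(x, rateHz) {
  colMeans(perSecondMatrix(x, rateHz))
}

#' Per-second spectral features of the heave axis
#'
#' Windowed discrete Fourier spectrum of the heave channel: for each
#' \code{windowS}-second window the DC term is excluded and the dominant
#' cycle (1 / argmax frequency) and its amplitude (2 |X_k| / N) are
#' returned. Windows containing missing samples yield missing features.
#'
#' @param heave numeric heave series in g.
#' @param rateHz sampling rate (Hz), at least 10.
#' @param windowS window length (s).
#' @return data.frame with \code{second} (0-based window index),
#'   \code{dominant_cycle_s} and \code{cycle_amplitude_g}.
#' @export
heaveSpectralFeatures <- function(heave, rateHz, windowS = 1) {
  if (rateHz < 10) stop("spectral features need rateHz >= 10")
  N <- round(rateHz * windowS)
  M <- perSecondMatrix(heave, N)
  ns <- ncol(M)
  kmax <- N %/% 2
  hasNA <- colSums(is.na(M)) > 0
  M[, hasNA] <- 0
  sp <- stats::mvfft(M)
  amp <- 2 * Mod(sp[2:(kmax + 1), , drop = FALSE]) / N
  dom <- max.col(t(amp), ties.method = "first")
  out <- data.frame(second = seq_len(ns) - 1L,
                    dominant_cycle_s = windowS / dom,
                    cycle_amplitude_g = amp[cbind(dom, seq_len(ns))])
  out$dominant_cycle_s[hasNA] <- NA_real_
  out$cycle_amplitude_g[hasNA] <- NA_real_
  out
}

#' Separate flapping from non-flapping seconds by k-means
#'
#' k-means (default k = 2, 10 restarts) on the standardized per-second
#' spectral features; the cluster with the higher mean cycle amplitude is
#' called flapping. Deterministic under a fixed seed. If all feature vectors
#' are identical no flapping is flagged, with a warning.
#'
#' @param features data.frame from [heaveSpectralFeatures()].
#' @param k number of clusters.
#' @param seed integer seed for the k-means restarts.
#' @return logical vector, one flag per second (NA features give FALSE).
#' @export
clusterFlapping <- function(features, k = 2, seed = 1) {
  X <- cbind(features$dominant_cycle_s, features$cycle_amplitude_g)
  ok <- stats::complete.cases(X)
  flags <- logical(nrow(X))
  Xok <- X[ok, , drop = FALSE]
  if (nrow(unique(Xok)) < k) {
    warning("identical spectral features; no flapping flagged")
    return(flags)
  }
  Xs <- scale(Xok)
  Xs[, apply(Xok, 2, stats::sd) == 0] <- 0
  km <- local({
    set.seed(seed)
    stats::kmeans(Xs, centers = k, nstart = 10, iter.max = 50)
  })
  ampMean <- tapply(Xok[, 2], km$cluster, mean)
  flapCluster <- as.integer(names(ampMean)[which.max(ampMean)])
  flags[ok] <- km$cluster == flapCluster
  flags
}

# 3-second majority vote on labels: a second flanked by two agreeing,
# different neighbours takes their label.
smoothLabels3 <- function(labels) {
  n <- length(labels)
  if (n < 3) return(labels)
  mid <- 2:(n - 1)
  flip <- labels[mid - 1] == labels[mid + 1] & labels[mid - 1] != labels[mid]
  labels[mid][flip] <- labels[mid - 1][flip]
  labels
}

#' Classify each second as flapping, soaring or rafting
#'
#' Rule-based ethogram on top of the k-means flap separation: a second is
#' \code{flap} when flagged as flapping; otherwise \code{raft} when its raw
#' heave standard deviation is at most \code{cfg$tauWaterG} and its static
#' heave lies in the on-water band \code{cfg$waterBandG}; otherwise
#' \code{glide}. A 3 s majority vote then removes single-second flicker.
#'
#' @param flappingFlag logical per-second flags from [clusterFlapping()].
#' @param heaveSd per-second standard deviation of the raw heave (g).
#' @param staticHeaveMean per-second mean static heave (g).
#' @param cfg an [analysisConfig()].
#' @return character vector of labels (\code{flap}, \code{glide},
#'   \code{raft}), one per second.
#' @export
classifyBehaviour <- function(flappingFlag, heaveSd, staticHeaveMean,
                              cfg = analysisConfig()) {
  if (is.null(cfg$tauWaterG) || is.null(cfg$waterBandG))
    stop("configuration error: tauWaterG / waterBandG unset")
  onWater <- heaveSd <= cfg$tauWaterG &
    staticHeaveMean >= cfg$waterBandG[1] &
    staticHeaveMean <= cfg$waterBandG[2]
  labels <- ifelse(flappingFlag, "flap", ifelse(onWater, "raft", "glide"))
  labels[is.na(labels)] <- "glide"
  smoothLabels3(labels)
}

#' Detect foraging seconds
#'
#' A second is foraging when the bird is not flying (label \code{raft}) and
#' its within-second minimum body pitch drops below
#' \code{cfg$pitchThresholdDeg} (default -25 degrees); the minimum (rather
#' than the mean) keeps 1-2 sample strikes from being averaged away.
#' Dive seconds detected from pressure, when supplied, are also marked.
#'
#' @param labels per-second ethogram labels.
#' @param pitchMinDeg per-second minimum body pitch (degrees).
#' @param cfg an [analysisConfig()].
#' @param diveSeconds optional integer vector of 0-based dive seconds from
#'   the pressure channel.
#' @return logical vector, one flag per second.
#' @export
detectForaging <- function(labels, pitchMinDeg, cfg = analysisConfig(),
                           diveSeconds = NULL) {
  f <- labels == "raft" & !is.na(pitchMinDeg) &
    pitchMinDeg < cfg$pitchThresholdDeg
  if (!is.null(diveSeconds)) {
    idx <- diveSeconds + 1L
    idx <- idx[idx >= 1 & idx <= length(f)]
    f[idx] <- f[idx] | labels[idx] != "flap"
  }
  f
}

#' Segment foraging seconds into events
#'
#' Foraging seconds separated by at most \code{gapS} seconds merge into one
#' event; a longer gap starts a new event. An event containing a dive second
#' is typed \code{dive}, otherwise \code{surface}. When an interpolated
#' track is supplied, the location at the event start is attached.
#'
#' @param isForaging logical per-second foraging flags.
#' @param gapS merge gap (s), default 5 (a 5 s gap still merges; 6 s splits).
#' @param denseTrack optional data.frame from [interpolateTrip()] aligned to
#'   the same clock (row i = second i - 1).
#' @param diveSeconds optional 0-based dive seconds.
#' @return data.frame with \code{start_s}, \code{end_s}, \code{duration_s},
#'   \code{type} and, when located, \code{lat}, \code{lon}.
#' @export
segmentEvents <- function(isForaging, gapS = 5, denseTrack = NULL,
                          diveSeconds = NULL) {
  sec <- which(isForaging) - 1L
  if (!length(sec))
    return(data.frame(start_s = integer(), end_s = integer(),
                      duration_s = integer(), type = character()))
  newEvent <- c(TRUE, diff(sec) > gapS)
  id <- cumsum(newEvent)
  start <- tapply(sec, id, min)
  end <- tapply(sec, id, max)
  type <- rep("surface", length(start))
  if (!is.null(diveSeconds) && length(diveSeconds)) {
    for (i in seq_along(start))
      if (any(diveSeconds >= start[i] & diveSeconds <= end[i]))
        type[i] <- "dive"
  }
  ev <- data.frame(start_s = as.integer(start), end_s = as.integer(end),
                   duration_s = as.integer(end - start + 1L), type = type)
  if (!is.null(denseTrack)) {
    idx <- pmin(ev$start_s + 1L, nrow(denseTrack))
    ev$lat <- denseTrack$lat[idx]
    ev$lon <- denseTrack$lon[idx]
  }
  rownames(ev) <- NULL
  ev
}

#' Activity budget and diel profile
#'
#' Percentage of trip seconds in each ethogram class (flap + raft + glide
#' sum to 100), with foraging reported separately because foraging seconds
#' overlap the rafting/diving classes. When the record start time and a
#' longitude are given, an hourly profile in local solar time
#' (UTC + lon/15 h) is included.
#'
#' @param labels per-second ethogram labels.
#' @param isForaging logical per-second foraging flags.
#' @param startTime optional POSIXct start of the record (UTC).
#' @param lon optional longitude for local solar time (degrees).
#' @return list with \code{proportionsPct} (named numeric), \code{foragingPct}
#'   and, when timed, \code{hourly} (data.frame hour x class percentages).
#' @export
activityBudget <- function(labels, isForaging, startTime = NULL, lon = NULL) {
  n <- length(labels)
  classes <- c("flap", "raft", "glide")
  pct <- vapply(classes, function(cl) 100 * sum(labels == cl) / n, numeric(1))
  out <- list(proportionsPct = pct,
              foragingPct = 100 * sum(isForaging) / n)
  if (!is.null(startTime) && !is.null(lon)) {
    solarH <- (as.numeric(format(startTime, "%H", tz = "UTC")) +
                 as.numeric(format(startTime, "%M", tz = "UTC")) / 60 +
                 (seq_len(n) - 1) / 3600 + solarOffsetH(lon)) %% 24
    hour <- floor(solarH)
    hourly <- do.call(rbind, lapply(sort(unique(hour)), function(h) {
      sel <- hour == h
      data.frame(hour = h,
                 flap = 100 * mean(labels[sel] == "flap"),
                 raft = 100 * mean(labels[sel] == "raft"),
                 glide = 100 * mean(labels[sel] == "glide"),
                 foraging = 100 * mean(isForaging[sel]))
    }))
    out$hourly <- hourly
  }
  out
}

#' Foraging rate and spacing
#'
#' Number of foraging events per hour of trip, and the average distance
#' between events when the trip length is known.
#'
#' @param nEvents number of foraging events.
#' @param tripDurationH trip duration (h), > 0.
#' @param totalDistanceKm optional total horizontal distance (km).
#' @return list with \code{eventsPerH} and \code{kmPerEvent} (NA when there
#'   are no events or no distance).
#' @export
foragingRate <- function(nEvents, tripDurationH, totalDistanceKm = NULL) {
  if (tripDurationH <= 0) stop("trip duration must be positive")
  list(eventsPerH = nEvents / tripDurationH,
       kmPerEvent = if (nEvents > 0 && !is.null(totalDistanceKm))
         totalDistanceKm / nEvents else NA_real_)
}

#' Build the full per-second ethogram for a deployment
#'
#' Runs the acceleration pipeline end to end: static/dynamic decomposition,
#' body pitch, VeDBA, heave spectral features, k-means flap separation,
#' rule-based classification with 3 s smoothing, and pitch-based foraging
#' detection (augmented with pressure-detected dive seconds when supplied).
#'
#' @param trace an \linkS4class{AccelTrace}.
#' @param cfg an [analysisConfig()].
#' @param seed integer seed for the k-means restarts.
#' @param diveSeconds optional 0-based dive seconds from [detectDives()].
#' @return data.frame, one row per complete second: \code{second},
#'   \code{label}, \code{is_foraging}, \code{pitch_deg} (within-second
#'   minimum), \code{vedba_g} (mean), \code{dominant_cycle_s},
#'   \code{cycle_amplitude_g}, \code{flapping_flag}.
#' @export
buildEthogram <- function(trace, cfg = analysisConfig(), seed = 1,
                          diveSeconds = NULL) {
  rate <- rateHz(trace)
  sd <- decomposeAcceleration(trace, cfg$decomposeWindowS)
  pitch <- bodyPitch(sd)
  ved <- vedba(sd)
  feat <- heaveSpectralFeatures(trace@az, rate, windowS = 1)
  flags <- clusterFlapping(feat, k = cfg$kmeansK, seed = seed)
  Mraw <- perSecondMatrix(trace@az, rate)
  heaveSd <- sqrt(pmax(0, colMeans(Mraw^2) - colMeans(Mraw)^2) *
                    rate / (rate - 1))
  staticMean <- perSecondMeans(sd$static$az, rate)
  labels <- classifyBehaviour(flags, heaveSd, staticMean, cfg)
  Mp <- perSecondMatrix(pitch, rate)
  pitchMin <- Reduce(pmin, lapply(seq_len(nrow(Mp)), function(i) Mp[i, ]))
  isForaging <- detectForaging(labels, pitchMin, cfg, diveSeconds)
  data.frame(second = feat$second, label = labels, is_foraging = isForaging,
             pitch_deg = pitchMin, vedba_g = perSecondMeans(ved, rate),
             dominant_cycle_s = feat$dominant_cycle_s,
             cycle_amplitude_g = feat$cycle_amplitude_g,
             flapping_flag = flags)
}
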
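#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GpsTrack: timestamped location fixes for one deployment
#'
#' Ordered GPS fixes (UTC timestamp, latitude, longitude) for a single logger
#' deployment. Timestamps must be strictly increasing and coordinates within
#' the WGS-84 bounds; all geometry downstream is geodesic (no projection).
#'
#' @slot fixes data.frame with columns \code{time} (POSIXct, UTC),
#'   \code{lat}, \code{lon} (decimal degrees).
#' @slot deploymentId character scalar identifying the deployment.
#'
#' @seealso [readGps()], [filterSpeed()], [segmentTrips()]
#' @export
setClass("GpsTrack",
  representation(fixes = "data.frame", deploymentId = "character"),
  validity = function(object) {
    f <- object@fixes
    msg <- character()
    if (!all(c("time", "lat", "lon") %in% names(f)))
      msg <- c(msg, "fixes must have columns time, lat, lon")
    else {
      if (!inherits(f$time, "POSIXct"))
        msg <- c(msg, "fixes$time must be POSIXct")
      if (nrow(f) > 1 && any(diff(as.numeric(f$time)) <= 0))
        msg <- c(msg, "timestamps must be strictly increasing")
      if (any(f$lat < -90 | f$lat > 90, na.rm = TRUE))
        msg <- c(msg, "latitude outside [-90, 90]")
      if (any(f$lon < -180 | f$lon > 180, na.rm = TRUE))
        msg <- c(msg, "longitude outside [-180, 180]")
    }
    if (length(object@deploymentId) != 1)
      msg <- c(msg, "deploymentId must be a single string")
    if (length(msg)) msg else TRUE
  }
)

#' AccelTrace: tri-axial acceleration (and optional pressure) for one deployment
#'
#' Raw 25 Hz (default) tri-axial acceleration in g. Axis convention follows
#' animal-borne tags: \code{ax} = surge (anterior positive), \code{ay} = sway,
#' \code{az} = heave (dorsal positive). An optional co-deployed pressure
#' channel (mBar, typically 1 Hz) supports dive detection.
#'
#' @slot startTime POSIXct start of the record (UTC).
#' @slot rateHz sampling rate of the acceleration channels (Hz).
#' @slot ax,ay,az numeric vectors of equal length, in g.
#' @slot pressure optional numeric vector in mBar, or NULL.
#' @slot pressureRateHz sampling rate of the pressure channel (Hz).
#' @slot deploymentId character scalar.
#'
#' @seealso [readAccel()], [decomposeAcceleration()], [buildEthogram()]
#' @export
setClass("AccelTrace",
  representation(
    startTime = "POSIXct", rateHz = "numeric",
    ax = "numeric", ay = "numeric", az = "numeric",
    pressure = "numericOrNULL", pressureRateHz = "numeric",
    deploymentId = "character"
  ),
  validity = function(object) {
    msg <- character()
    n <- length(object@ax)
    if (length(object@ay) != n || length(object@az) != n)
      msg <- c(msg, "ax, ay, az must have equal length")
    if (length(object@rateHz) != 1 || object@rateHz <= 0)
      msg <- c(msg, "rateHz must be a single positive number")
    if (!is.null(object@pressure)) {
      if (length(object@pressureRateHz) != 1 || object@pressureRateHz <= 0)
        msg <- c(msg, "pressureRateHz must be positive when pressure present")
      else {
        expect <- n / object@rateHz * object@pressureRateHz
        if (abs(length(object@pressure) - expect) > object@pressureRateHz)
          msg <- c(msg, "pressure length inconsistent with its rate")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' GroundTruth: simulated per-second labels and event logs
#'
#' Ground truth emitted alongside a synthetic deployment: one behaviour label
#' per simulated second (flap, glide, raft, forage_surface, dive), the dive
#' log (start, duration, max depth) and the foraging-event log. Used to score
#' the ethogram classifier and the dive detector.
#'
#' @slot labels character vector, one label per second.
#' @slot diveLog data.frame: \code{start_s}, \code{duration_s},
#'   \code{max_depth_m}.
#' @slot eventLog data.frame: \code{start_s}, \code{end_s}, \code{type}.
#' @export
setClass("GroundTruth",
  representation(labels = "character", diveLog = "data.frame",
                 eventLog = "data.frame"),
  validity = function(object) {
    msg <- character()
    ok <- c("flap", "glide", "raft", "forage_surface", "dive")
    if (!all(object@labels %in% ok))
      msg <- c(msg, "unknown behaviour label")
    if (nrow(object@diveLog) && any(object@diveLog$max_depth_m <= 0.55))
      msg <- c(msg, "dive log contains max_depth <= 0.55 m")
    if (length(msg)) msg else TRUE
  }
)

#' Trip: one central-place foraging trip
#'
#' A maximal run of at-sea fixes outside the colony radius, bracketed by the
#' nearest fixes inside it, cut from a [GpsTrack-class].
#'
#' @slot fixes data.frame as in [GpsTrack-class].
#' @slot deploymentId character scalar.
#' @slot tripId integer index of the trip within the deployment.
#' @export
setClass("Trip",
  representation(fixes = "data.frame", deploymentId = "character",
                 tripId = "integer"),
  validity = function(object) {
    if (nrow(object@fixes) < 3) "a trip needs at least 3 fixes" else TRUE
  }
)
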
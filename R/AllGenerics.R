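#' Accessors for biologging objects
#'
#' Accessor generics for the S4 containers: \code{fixes()} returns the
#' fix table of a track or trip, \code{deploymentId()} the deployment
#' identifier, \code{rateHz()} the acceleration sampling rate,
#' \code{startTime()} the record start, \code{pressureSeries()} the raw
#' pressure channel (or NULL), and \code{truthLabels()} the per-second
#' ground-truth labels of a synthetic deployment.
#'
#' @param x a \linkS4class{GpsTrack}, \linkS4class{AccelTrace},
#'   \linkS4class{Trip} or \linkS4class{GroundTruth} object.
#' @return The slot contents (see Details of each class).
#' @name accessors
#' @aliases fixes deploymentId rateHz startTime pressureSeries truthLabels
#' @examples
#' trk <- gpsTrack(
#'   time = as.POSIXct("2016-08-12", tz = "UTC") + c(0, 300, 600),
#'   lat = c(-42.1, -42.2, -42.3), lon = c(171.3, 171.2, 171.1))
#' nrow(fixes(trk))
NULL

#' @rdname accessors
#' @export
setGeneric("fixes", function(x) standardGeneric("fixes"))
#' @rdname accessors
#' @export
setGeneric("deploymentId", function(x) standardGeneric("deploymentId"))
#' @rdname accessors
#' @export
setGeneric("rateHz", function(x) standardGeneric("rateHz"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("pressureSeries", function(x) standardGeneric("pressureSeries"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname accessors
setMethod("fixes", "GpsTrack", function(x) x@fixes)
#' @rdname accessors
setMethod("fixes", "Trip", function(x) x@fixes)
#' @rdname accessors
setMethod("deploymentId", "GpsTrack", function(x) x@deploymentId)
#' @rdname accessors
setMethod("deploymentId", "AccelTrace", function(x) x@deploymentId)
#' @rdname accessors
setMethod("deploymentId", "Trip", function(x) x@deploymentId)
#' @rdname accessors
setMethod("rateHz", "AccelTrace", function(x) x@rateHz)
#' @rdname accessors
setMethod("startTime", "AccelTrace", function(x) x@startTime)
#' @rdname accessors
setMethod("pressureSeries", "AccelTrace", function(x) x@pressure)
#' @rdname accessors
setMethod("truthLabels", "GroundTruth", function(x) x@labels)

setMethod("show", "GpsTrack", function(object) {
  f <- object@fixes
  cat("GpsTrack '", object@deploymentId, "': ", nrow(f), " fixes", sep = "")
  if (nrow(f)) {
    cat(" | ", format(f$time[1], "%Y-%m-%d %H:%M", tz = "UTC"), " .. ",
        format(f$time[nrow(f)], "%Y-%m-%d %H:%M", tz = "UTC"), " UTC", sep = "")
  }
  cat("\n")
})

setMethod("show", "AccelTrace", function(object) {
  n <- length(object@ax)
  cat("AccelTrace '", object@deploymentId, "': ", n, " samples @ ",
      object@rateHz, " Hz (", round(n / object@rateHz / 3600, 2), " h)",
      sep = "")
  if (!is.null(object@pressure))
    cat(" + pressure @", object@pressureRateHz, "Hz")
  cat("\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@labels), "labelled seconds,",
      nrow(object@eventLog), "foraging events,",
      nrow(object@diveLog), "dives\n")
})

setMethod("show", "Trip", function(object) {
  f <- object@fixes
  dur <- as.numeric(difftime(f$time[nrow(f)], f$time[1], units = "hours"))
  cat("Trip ", object@tripId, " of '", object@deploymentId, "': ",
      nrow(f), " fixes, ", round(dur, 1), " h\n", sep = "")
})

#' Construct a GpsTrack
#'
#' @param time POSIXct vector (UTC) of fix timestamps.
#' @param lat,lon numeric vectors of decimal degrees.
#' @param deploymentId identifier string.
#' @return A \linkS4class{GpsTrack}.
#' @export
gpsTrack <- function(time, lat, lon, deploymentId = "dep1") {
  new("GpsTrack",
      fixes = data.frame(time = time, lat = as.numeric(lat),
                         lon = as.numeric(lon)),
      deploymentId = as.character(deploymentId))
}

#' Construct an AccelTrace
#'
#' @param ax,ay,az numeric acceleration vectors in g (surge, sway, heave).
#' @param rateHz acceleration sampling rate (Hz).
#' @param startTime POSIXct start of the record.
#' @param pressure optional pressure vector in mBar.
#' @param pressureRateHz pressure sampling rate (Hz).
#' @param deploymentId identifier string.
#' @return An \linkS4class{AccelTrace}.
#' @export
accelTrace <- function(ax, ay, az, rateHz = 25,
                       startTime = as.POSIXct("2016-08-12 00:00:00",
                                              tz = "UTC"),
                       pressure = NULL, pressureRateHz = 1,
                       deploymentId = "dep1") {
  new("AccelTrace", startTime = startTime, rateHz = rateHz,
      ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
      pressure = if (is.null(pressure)) NULL else as.numeric(pressure),
      pressureRateHz = pressureRateHz,
      deploymentId = as.character(deploymentId))
}
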
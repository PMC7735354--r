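# Readers and writers for the delimited-text biologging formats. Comma is the
# default separator; tab-separated files are accepted everywhere.

readDelimited <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

requireColumns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
}

parseUtc <- function(x, path) {
  x <- as.character(x)
  t <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                  tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d")) {
    miss <- is.na(t)
    if (!any(miss)) break
    t[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  bad <- which(is.na(t))
  if (length(bad))
    stop("schema error in ", path, ": unparsable timestamp at data row ",
         bad[1], " ('", x[bad[1]], "')")
  t
}

#' Read a GPS log
#'
#' Reads a delimited text file with header columns \code{time} (ISO-8601,
#' UTC), \code{lat} and \code{lon}, validating monotone timestamps and
#' coordinate bounds.
#'
#' @param path file path.
#' @param deploymentId identifier to attach; defaults to the file name.
#' @return A \linkS4class{GpsTrack}.
#' @export
readGps <- function(path, deploymentId = NULL) {
  df <- readDelimited(path)
  requireColumns(df, c("time", "lat", "lon"), path)
  t <- parseUtc(df$time, path)
  if (nrow(df) > 1) {
    reg <- which(diff(as.numeric(t)) <= 0)
    if (length(reg))
      stop("schema error in ", path, ": non-increasing timestamp at data row ",
           reg[1] + 1)
  }
  gpsTrack(time = t, lat = df$lat, lon = df$lon,
           deploymentId = deploymentId %||% basename(path))
}

#' Write a GPS track
#'
#' @param track a \linkS4class{GpsTrack}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGps <- function(track, path) {
  f <- fixes(track)
  out <- data.frame(time = format(f$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    lat = sprintf("%.6f", f$lat),
                    lon = sprintf("%.6f", f$lon))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an acceleration log
#'
#' Reads a delimited file with columns \code{ax}, \code{ay}, \code{az} (g).
#' An optional \code{pressure} column (mBar) may be present; because pressure
#' is usually sampled slower than acceleration, trailing missing values in
#' that column are dropped to recover the 1 Hz series.
#'
#' @param path file path.
#' @param rateHz acceleration sampling rate (Hz).
#' @param startTime POSIXct start of the record (UTC).
#' @param pressureRateHz pressure sampling rate (Hz).
#' @param deploymentId identifier; defaults to the file name.
#' @return An \linkS4class{AccelTrace}.
#' @export
readAccel <- function(path, rateHz = 25,
                      startTime = as.POSIXct("2016-08-12 00:00:00",
                                             tz = "UTC"),
                      pressureRateHz = 1, deploymentId = NULL) {
  df <- readDelimited(path)
  requireColumns(df, c("ax", "ay", "az"), path)
  for (col in c("ax", "ay", "az")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("schema error in ", path, ": non-numeric ", col, " at data row ",
           bad[1])
  }
  pres <- NULL
  if ("pressure" %in% names(df)) {
    pres <- df$pressure[!is.na(df$pressure)]
    if (!length(pres)) pres <- NULL
  }
  accelTrace(df$ax, df$ay, df$az, rateHz = rateHz, startTime = startTime,
             pressure = pres, pressureRateHz = pressureRateHz,
             deploymentId = deploymentId %||% basename(path))
}

#' Write an acceleration trace
#'
#' @param trace an \linkS4class{AccelTrace}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAccel <- function(trace, path) {
  n <- length(trace@ax)
  out <- data.frame(ax = trace@ax, ay = trace@ay, az = trace@az)
  if (!is.null(trace@pressure)) {
    p <- rep(NA_real_, n)
    p[seq_along(trace@pressure)] <- trace@pressure
    out$pressure <- p
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read per-bird morphometric or isotope tables
#'
#' \code{readMorphoTable()} expects columns \code{bird_id}, \code{sex},
#' \code{culmen_depth_mm}, \code{culmen_width_mm}, \code{culmen_length_mm},
#' \code{wing_length_mm}, \code{tarsus_length_mm}, \code{mass_g};
#' \code{readIsotopeTable()} expects \code{bird_id}, \code{sex}, \code{year},
#' \code{d15N}, \code{d13C} (one row per bird-year).
#'
#' @param path file path.
#' @return A validated data.frame.
#' @export
readMorphoTable <- function(path) {
  df <- readDelimited(path)
  requireColumns(df, c("bird_id", "sex", "culmen_depth_mm", "culmen_width_mm",
                       "culmen_length_mm", "wing_length_mm",
                       "tarsus_length_mm", "mass_g"), path)
  if (!all(df$sex %in% c("male", "female")))
    stop("schema error in ", path, ": sex must be 'male' or 'female'")
  meas <- df[, c("culmen_depth_mm", "culmen_width_mm", "culmen_length_mm",
                 "wing_length_mm", "tarsus_length_mm", "mass_g")]
  if (any(as.matrix(meas) <= 0, na.rm = TRUE))
    stop("schema error in ", path, ": non-positive measurement")
  df
}

#' @rdname readMorphoTable
#' @export
readIsotopeTable <- function(path) {
  df <- readDelimited(path)
  requireColumns(df, c("bird_id", "sex", "year", "d15N", "d13C"), path)
  if (anyDuplicated(df[, c("bird_id", "year")]))
    stop("schema error in ", path, ": duplicate bird-year row")
  if (any(!is.finite(df$d15N)) || any(!is.finite(df$d13C)))
    stop("schema error in ", path, ": non-finite isotope value")
  df
}

#' Write pipeline result tables to a directory
#'
#' Writes each element of \code{results} (data.frames) as a CSV named after
#' the element, with deterministic column order and row order as given.
#'
#' @param results named list of data.frames.
#' @param dir output directory (created if absent).
#' @return character vector of file paths, invisibly.
#' @export
writeOutputs <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], p, row.names = FALSE, quote = FALSE,
                     na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export point locations as well-known text
#'
#' Writes a delimited table with a WKT \code{POINT (lon lat)} geometry column,
#' a simple interchange format GIS tools read directly.
#'
#' @param df data.frame with \code{lat} and \code{lon} columns.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePointsWkt <- function(df, path) {
  stopifnot(all(c("lat", "lon") %in% names(df)))
  out <- df[, setdiff(names(df), c("lat", "lon")), drop = FALSE]
  out$WKT <- sprintf("POINT (%.6f %.6f)", df$lon, df$lat)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
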
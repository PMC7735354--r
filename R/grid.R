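#' Grid standardized foraging time
#'
#' Sums foraging seconds localized on the interpolated track into square
#' grid cells of \code{cellDeg} degrees (default 0.04, ca 4 km^2) and
#' standardizes them to percentages of the trip's total foraging time.
#' Cells are half-open intervals \code{[k*cellDeg, (k+1)*cellDeg)} anchored
#' at 0 degrees, so a point exactly on an edge belongs to the floor cell.
#'
#' @param denseTrack data.frame from [interpolateTrip()] with \code{lat},
#'   \code{lon} and a logical \code{is_foraging} column (one row per second).
#' @param cellDeg grid cell size (degrees).
#' @return data.frame with cell indices \code{i} (lat), \code{j} (lon), cell
#'   centers \code{lat}, \code{lon}, \code{foraging_s} and
#'   \code{pct_foraging_time} (summing to 100). No foraging returns an empty
#'   frame with a message.
#' @export
gridForagingTime <- function(denseTrack, cellDeg = 0.04) {
  stopifnot(all(c("lat", "lon", "is_foraging") %in% names(denseTrack)))
  f <- denseTrack[denseTrack$is_foraging, , drop = FALSE]
  if (!nrow(f)) {
    message("no foraging seconds to grid")
    return(data.frame(i = integer(), j = integer(), lat = numeric(),
                      lon = numeric(), foraging_s = numeric(),
                      pct_foraging_time = numeric()))
  }
  i <- floor(f$lat / cellDeg)
  j <- floor(f$lon / cellDeg)
  key <- paste(i, j)
  agg <- stats::aggregate(list(foraging_s = rep(1, nrow(f))),
                          by = list(i = i, j = j), FUN = sum)
  agg$lat <- (agg$i + 0.5) * cellDeg
  agg$lon <- (agg$j + 0.5) * cellDeg
  agg$pct_foraging_time <- 100 * agg$foraging_s / sum(agg$foraging_s)
  agg[order(-agg$pct_foraging_time),
      c("i", "j", "lat", "lon", "foraging_s", "pct_foraging_time")]
}

#' Construct a gridded covariate layer
#'
#' A regular lat/lon raster of one environmental variable with one or more
#' validity times, for spatio-temporal matching against foraging grid cells.
#'
#' @param name variable name.
#' @param lats,lons increasing vectors of cell-center coordinates (degrees).
#' @param times POSIXct validity time of each slice.
#' @param values numeric array dim c(length(lats), length(lons),
#'   length(times)); a matrix is accepted for a single time slice.
#' @return list of class \code{"covariateLayer"}.
#' @export
covariateLayer <- function(name, lats, lons, times, values) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1))
  if (!is.array(values) || length(dim(values)) != 3)
    stop("format error: values must be a lat x lon x time array")
  if (!all(dim(values) == c(length(lats), length(lons), length(times))))
    stop("format error: values dimensions do not match lats/lons/times")
  if (is.unsorted(lats) || is.unsorted(lons))
    stop("format error: lats and lons must be increasing")
  structure(list(name = name, lats = as.numeric(lats),
                 lons = as.numeric(lons), times = times, values = values),
            class = "covariateLayer")
}

#' Read a covariate layer from long-format delimited text
#'
#' Expects columns \code{lat}, \code{lon}, \code{time} (ISO-8601 UTC) and
#' \code{value} on a complete regular grid.
#'
#' @param path file path.
#' @param name variable name; defaults to the file name.
#' @return a [covariateLayer()].
#' @export
readCovariateLayer <- function(path, name = NULL) {
  df <- readDelimited(path)
  requireColumns(df, c("lat", "lon", "time", "value"), path)
  t <- parseUtc(df$time, path)
  lats <- sort(unique(df$lat))
  lons <- sort(unique(df$lon))
  times <- sort(unique(t))
  arr <- array(NA_real_, dim = c(length(lats), length(lons), length(times)))
  arr[cbind(match(df$lat, lats), match(df$lon, lons), match(t, times))] <-
    df$value
  if (anyNA(arr)) stop("format error: incomplete grid in ", path)
  covariateLayer(name %||% basename(path), lats, lons, times, arr)
}

nearestIndex <- function(x, grid, spacing) {
  idx <- findInterval(x, grid + c(diff(grid) / 2, Inf)) + 1L
  out <- ifelse(x < grid[1] - spacing / 2 |
                  x > grid[length(grid)] + spacing / 2, NA_integer_, idx)
  out
}

#' Match environmental covariates to foraging grid cells
#'
#' For each foraging cell, looks up the nearest-neighbour raster cell of
#' each layer in its temporally nearest slice to the trip mid-time. Cells
#' outside a layer's extent give missing values, never silent zeros.
#'
#' @param cells data.frame from [gridForagingTime()].
#' @param layers list of [covariateLayer()] objects.
#' @param tripMidTime POSIXct mid-time of the trip.
#' @return \code{cells} with one extra column per layer, plus a Spearman
#'   rank-correlation matrix of the matched covariates as attribute
#'   \code{"covariateCor"} (reported for collinearity screening; nothing is
#'   dropped automatically).
#' @export
matchEnvironment <- function(cells, layers, tripMidTime) {
  out <- cells
  for (ly in layers) {
    if (!inherits(ly, "covariateLayer"))
      stop("format error: layers must be covariateLayer objects")
    ti <- which.min(abs(as.numeric(ly$times) - as.numeric(tripMidTime)))
    dLat <- if (length(ly$lats) > 1) min(diff(ly$lats)) else 1e-6
    dLon <- if (length(ly$lons) > 1) min(diff(ly$lons)) else 1e-6
    li <- nearestIndex(cells$lat, ly$lats, dLat)
    lj <- nearestIndex(cells$lon, ly$lons, dLon)
    v <- rep(NA_real_, nrow(cells))
    ok <- !is.na(li) & !is.na(lj)
    v[ok] <- ly$values[cbind(li[ok], lj[ok], ti)]
    out[[ly$name]] <- v
  }
  covNames <- vapply(layers, `[[`, character(1), "name")
  if (length(covNames) > 1 && nrow(out) > 2) {
    attr(out, "covariateCor") <-
      suppressWarnings(stats::cor(out[, covNames], method = "spearman",
                                  use = "pairwise.complete.obs"))
  }
  out
}
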
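#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline in one validated list.
#' Defaults follow standard practice for flap-gliding Procellariiformes
#' tracked with GPS + 25 Hz accelerometers + 1 Hz pressure loggers:
#'
#' \itemize{
#'   \item \code{speedFilterMs} (25 m/s): forward speed filter removing
#'     erroneous GPS fixes.
#'   \item \code{interpIntervalS} (1 s): linear track interpolation step.
#'   \item \code{decomposeWindowS} (1 s): running-mean window separating the
#'     static (gravitational) from the dynamic acceleration component.
#'   \item \code{pitchThresholdDeg} (-25): body-pitch threshold below which a
#'     non-flying second counts as foraging (head-down prey seizing).
#'   \item \code{eventGapS} (5 s): foraging seconds closer than this merge
#'     into one foraging event.
#'   \item \code{diveThresholdM} (0.55 m, one body length): minimum depth for
#'     a submergence to count as a dive (strict inequality).
#'   \item \code{descentRateMs} (0.84 m/s): fleet descent rate used to
#'     estimate depth from duration on pressure-less loggers.
#'   \item \code{gridCellDeg} (0.04 degrees, ca 4 km^2): habitat grid cell.
#'   \item \code{tauWaterG}, \code{waterBandG}: per-second raw-heave s.d.
#'     ceiling and static-heave band (g) that separate on-water seconds from
#'     soaring flight; calibrated on the synthetic biologger.
#'   \item \code{colony}, \code{colonyRadiusKm}: central place and the radius
#'     used to mask on-land/colony fixes and cut trips.
#'   \item \code{matchWindowS} (2 s): tolerance when matching
#'     acceleration-detected foraging events to pressure-detected dives.
#' }
#'
#' @param speedFilterMs,interpIntervalS,decomposeWindowS,pitchThresholdDeg
#'   numeric scalars, see Details.
#' @param eventGapS,diveThresholdM,descentRateMs,gridCellDeg numeric scalars.
#' @param colony numeric length-2 c(lat, lon) of the colony (decimal degrees).
#' @param colonyRadiusKm numeric, trip-cutting radius around the colony (km).
#' @param kmeansK number of k-means clusters for flap separation.
#' @param matchWindowS numeric, dive-validation match window (s).
#' @param tauWaterG numeric, raw-heave per-second s.d. ceiling for on-water (g).
#' @param waterBandG numeric length-2, static-heave band for on-water (g).
#' @param driftWindowS,driftQuantile surface-drift correction: rolling window
#'   (s) and lower quantile used as the zero-offset baseline.
#' @return A named list of class \code{"analysisConfig"}.
#' @examples
#' cfg <- analysisConfig()
#' cfg$diveThresholdM
#' @export
analysisConfig <- function(speedFilterMs = 25,
                           interpIntervalS = 1,
                           decomposeWindowS = 1,
                           pitchThresholdDeg = -25,
                           eventGapS = 5,
                           diveThresholdM = 0.55,
                           descentRateMs = 0.84,
                           gridCellDeg = 0.04,
                           colony = c(-42.146, 171.341),
                           colonyRadiusKm = 1,
                           kmeansK = 2,
                           matchWindowS = 2,
                           tauWaterG = 0.25,
                           waterBandG = c(0.45, 0.93),
                           driftWindowS = 600,
                           driftQuantile = 0.02) {
  cfg <- list(speedFilterMs = speedFilterMs, interpIntervalS = interpIntervalS,
              decomposeWindowS = decomposeWindowS,
              pitchThresholdDeg = pitchThresholdDeg, eventGapS = eventGapS,
              diveThresholdM = diveThresholdM, descentRateMs = descentRateMs,
              gridCellDeg = gridCellDeg, colony = colony,
              colonyRadiusKm = colonyRadiusKm, kmeansK = kmeansK,
              matchWindowS = matchWindowS, tauWaterG = tauWaterG,
              waterBandG = waterBandG, driftWindowS = driftWindowS,
              driftQuantile = driftQuantile)
  num <- unlist(cfg[c("speedFilterMs", "interpIntervalS", "decomposeWindowS",
                      "pitchThresholdDeg", "eventGapS", "diveThresholdM",
                      "descentRateMs", "gridCellDeg", "colonyRadiusKm",
                      "matchWindowS", "tauWaterG")])
  if (any(!is.finite(num)))
    stop("all thresholds must be finite")
  if (pitchThresholdDeg >= 0)
    stop("pitchThresholdDeg must be negative")
  if (gridCellDeg <= 0)
    stop("gridCellDeg must be positive")
  if (length(colony) != 2)
    stop("colony must be c(lat, lon)")
  if (length(waterBandG) != 2 || waterBandG[1] >= waterBandG[2])
    stop("waterBandG must be an increasing length-2 interval")
  structure(cfg, class = "analysisConfig")
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration with optional \code{analysis} and
#' \code{simulate} sections; unknown keys raise an error so typos do not
#' silently fall back to defaults.
#'
#' @param path path to the YAML file.
#' @return list with elements \code{analysis} (an [analysisConfig()]) and,
#'   when present, \code{simulate} (a [simConfig()]), plus any \code{io}
#'   section verbatim.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$analysis)) {
    known <- names(formals(analysisConfig))
    bad <- setdiff(names(raw$analysis), known)
    if (length(bad))
      stop("unknown analysis config keys: ", paste(bad, collapse = ", "))
    out$analysis <- do.call(analysisConfig, raw$analysis)
  } else out$analysis <- analysisConfig()
  if (!is.null(raw$simulate)) {
    known <- names(formals(simConfig))
    bad <- setdiff(names(raw$simulate), known)
    if (length(bad))
      stop("unknown simulate config keys: ", paste(bad, collapse = ", "))
    out$simulate <- do.call(simConfig, raw$simulate)
  }
  out$io <- raw$io
  out
}
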
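#' Run the full biologging analysis pipeline
#'
#' Orchestrates every stage on one deployment: GPS speed filter, trip
#' segmentation and metrics, 1 s interpolation, pressure/dive analysis (when
#' a pressure channel is present), per-second ethogram, foraging events,
#' activity budget, cross-sensor dive validation, gridded foraging effort
#' and, when bird tables are supplied, SSD and isotopic niche summaries.
#' Stages whose inputs are missing are skipped with a warning and downstream
#' stages degrade gracefully (e.g. a GPS-only run still yields trip tables).
#'
#' @param gps a \linkS4class{GpsTrack}, or NULL.
#' @param accel an \linkS4class{AccelTrace}, or NULL.
#' @param cfg an [analysisConfig()].
#' @param morpho,isotope optional bird tables ([readMorphoTable()] /
#'   [readIsotopeTable()] schemas).
#' @param layers optional list of [covariateLayer()] objects.
#' @param seed integer seed (k-means restarts, Bayesian ellipse draws).
#' @param outDir optional directory; when given, all result tables are
#'   written there as CSV together with \code{manifest.json}.
#' @return named list of result tables: \code{trips}, \code{ethogram},
#'   \code{events}, \code{dives}, \code{budget}, \code{grid}, \code{ssd},
#'   \code{niche}, \code{validationPct}, \code{manifest} (entries NULL when
#'   the stage was skipped).
#' @examples
#' dep <- simulateDeployment(simConfig(seed = 2, tripDurationH = 1))
#' res <- runPipeline(dep$gps, dep$accel, seed = 2)
#' res$trips
#' @export
runPipeline <- function(gps = NULL, accel = NULL, cfg = analysisConfig(),
                        morpho = NULL, isotope = NULL, layers = NULL,
                        seed = 1, outDir = NULL) {
  res <- list()

  ## trips -------------------------------------------------------------
  trips <- NULL
  dense <- NULL
  if (!is.null(gps)) {
    filtered <- filterSpeed(gps, cfg$speedFilterMs)
    trips <- segmentTrips(filtered, cfg)
    if (length(trips)) {
      res$trips <- do.call(rbind, lapply(trips, tripMetrics,
                                         colony = cfg$colony))
    } else warning("no trips found; trip stage empty")
    if (nrow(fixes(filtered)) >= 2)
      dense <- interpolateTrip(filtered, cfg$interpIntervalS)
  } else warning("no GPS input; trip stage skipped")

  ## dives --------------------------------------------------------------
  dives <- NULL
  diveSeconds <- NULL
  if (!is.null(accel) && !is.null(pressureSeries(accel))) {
    pr <- analyzePressure(accel, cfg)
    dives <- pr$dives
    res$dives <- dives
    if (nrow(dives))
      diveSeconds <- unlist(lapply(seq_len(nrow(dives)), function(i)
        seq(floor(dives$start_s[i]), ceiling(dives$end_s[i]))))
  }

  ## ethogram -----------------------------------------------------------
  if (!is.null(accel)) {
    eth <- buildEthogram(accel, cfg, seed = seed, diveSeconds = diveSeconds)
    # align the dense track to the acceleration clock: row s + 1 holds the
    # position at acceleration second s
    evDense <- NULL
    if (!is.null(dense)) {
      offset <- round(as.numeric(difftime(dense$time[1], startTime(accel),
                                          units = "secs")))
      m <- match(eth$second, round(dense$elapsed_s) + offset)
      evDense <- data.frame(lat = dense$lat[m], lon = dense$lon[m])
    }
    events <- segmentEvents(eth$is_foraging, cfg$eventGapS,
                            denseTrack = evDense, diveSeconds = diveSeconds)
    res$ethogram <- eth
    res$events <- events
    durH <- nrow(eth) / 3600
    bud <- activityBudget(eth$label, eth$is_foraging,
                          startTime = startTime(accel),
                          lon = cfg$colony[2])
    rate <- foragingRate(nrow(events), durH,
                         if (!is.null(res$trips))
                           sum(res$trips$total_distance_km) else NULL)
    res$budget <- data.frame(
      flap_pct = bud$proportionsPct[["flap"]],
      raft_pct = bud$proportionsPct[["raft"]],
      glide_pct = bud$proportionsPct[["glide"]],
      foraging_pct = bud$foragingPct,
      events_per_h = rate$eventsPerH, km_per_event = rate$kmPerEvent)
    res$hourly <- bud$hourly
    if (!is.null(dives))
      res$validationPct <- validateDetection(events, dives, cfg$matchWindowS)

    ## habitat grid ------------------------------------------------------
    if (!is.null(evDense)) {
      dt <- cbind(evDense, is_foraging = eth$is_foraging)
      dt <- dt[!is.na(dt$lat), , drop = FALSE]
      cells <- gridForagingTime(dt, cfg$gridCellDeg)
      if (!is.null(layers) && nrow(cells)) {
        mid <- dense$time[1] +
          as.numeric(difftime(dense$time[nrow(dense)], dense$time[1],
                              units = "secs")) / 2
        cells <- matchEnvironment(cells, layers, mid)
      }
      res$grid <- cells
    }
  } else warning("no acceleration input; ethogram stage skipped")

  ## niche metrics -------------------------------------------------------
  if (!is.null(morpho)) res$ssd <- ssdTable(morpho)
  if (!is.null(isotope)) {
    iso <- as.matrix(isotope[, c("d13C", "d15N")])
    sb <- seaB(iso, seed = seed)
    res$niche <- data.frame(
      n = nrow(iso), sea = standardEllipse(iso)$sea, sea_c = seaC(iso),
      sea_b_mean = sb$mean, sea_b_lo = sb$ci95[1], sea_b_hi = sb$ci95[2])
  }

  res$manifest <- buildManifest(cfg, seed, res)
  if (!is.null(outDir)) {
    tabs <- Filter(is.data.frame, res)
    writeOutputs(tabs, outDir)
    jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

# Run manifest: configuration fingerprint, seeds, package version and the
# tables produced, so every output is traceable.
buildManifest <- function(cfg, seed, res) {
  list(
    tool = "flapglide",
    version = as.character(utils::packageVersion("flapglide")),
    configHash = fnv1a32(paste(deparse(unclass(cfg)), collapse = "\n")),
    config = unclass(cfg),
    seed = seed,
    outputs = names(Filter(is.data.frame, res)),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}
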
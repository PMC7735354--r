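# Shared fixtures, built once per test session.

# A short synthetic deployment reused by the ethogram, dive and pipeline
# unit tests (the acceptance suite runs full-length deployments itself).
.fixtures <- new.env()

shortDeployment <- function() {
  if (is.null(.fixtures$dep)) {
    .fixtures$dep <- simulateDeployment(simConfig(seed = 42,
                                                  tripDurationH = 4))
  }
  .fixtures$dep
}

# Ground-truth labels collapsed to the classifier's 3 classes (foraging
# happens on water, so forage/dive seconds count as rafting).
collapseTruth <- function(labels) {
  ifelse(labels %in% c("forage_surface", "dive"), "raft", labels)
}

# Per-second classification accuracy of an ethogram against ground truth.
ethogramAccuracy <- function(eth, truth) {
  gt <- collapseTruth(truthLabels(truth))
  n <- min(nrow(eth), length(gt))
  mean(eth$label[seq_len(n)] == gt[seq_len(n)])
}

# A hand-built GPS track: fixes every 5 min along a line of latitude.
lineTrack <- function(nFix = 10, lat0 = -42, lon0 = 171, dLat = 0.01) {
  gpsTrack(time = as.POSIXct("2016-08-12", tz = "UTC") + 300 * (0:(nFix - 1)),
           lat = lat0 + dLat * (0:(nFix - 1)), lon = rep(lon0, nFix))
}
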
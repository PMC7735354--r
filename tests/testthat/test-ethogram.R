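test_that("static/dynamic decomposition is exact and removes fast cycles", {
  # constant signal: static = signal, dynamic = 0
  tr <- accelTrace(rep(0.2, 100), rep(-0.1, 100), rep(1, 100))
  sd <- decomposeAcceleration(tr, 1)
  expect_equal(sd$static$ax, rep(0.2, 100))
  expect_equal(sd$dynamic$az, rep(0, 100))

  # pure 5 Hz sine at 25 Hz: interior static stays near zero
  t <- (0:499) / 25
  tr2 <- accelTrace(rep(0, 500), rep(0, 500), sin(2 * pi * 5 * t))
  sd2 <- decomposeAcceleration(tr2, 1)
  interior <- 26:475
  expect_lt(max(abs(sd2$static$az[interior])), 0.05)

  # reconstruction is exact on arbitrary signals
  set.seed(1)
  tr3 <- accelTrace(rnorm(200), rnorm(200), rnorm(200))
  sd3 <- decomposeAcceleration(tr3, 1)
  expect_equal(sd3$static$ax + sd3$dynamic$ax, tr3@ax, tolerance = 1e-12)
  expect_error(decomposeAcceleration(accelTrace(1, 1, 1), 1), "shorter")
})

test_that("body pitch matches closed forms", {
  mk <- function(ax, ay, az) {
    n <- 75
    structure(list(static = list(ax = rep(ax, n), ay = rep(ay, n),
                                 az = rep(az, n)),
                   dynamic = list(ax = numeric(n), ay = numeric(n),
                                  az = numeric(n)), rateHz = 25),
              class = "staticDynamic")
  }
  expect_equal(bodyPitch(mk(0, 0, 1))[1], 0)
  expect_equal(bodyPitch(mk(1, 0, 0))[1], 90)
  expect_equal(bodyPitch(mk(-1, 0, 0))[1], -90)
  expect_equal(bodyPitch(mk(-0.5, 0, 0.866))[1], -30, tolerance = 1e-3)
  expect_true(is.na(bodyPitch(mk(0, 0, 0))[1]))
})

test_that("VeDBA is the dynamic norm and aggregates consistently", {
  n <- 50
  sd <- structure(list(
    static = list(ax = numeric(n), ay = numeric(n), az = numeric(n)),
    dynamic = list(ax = rep(0.3, n), ay = rep(0.4, n), az = numeric(n)),
    rateHz = 25), class = "staticDynamic")
  expect_equal(vedba(sd), rep(0.5, n))  # 3-4-5 triangle

  sd$dynamic <- list(ax = numeric(n), ay = numeric(n), az = numeric(n))
  expect_equal(vedba(sd), rep(0, n))

  # trip mean equals the mean of per-second means for complete seconds
  set.seed(2)
  x <- rnorm(250)
  expect_equal(mean(perSecondMeans(x, 25)), mean(x), tolerance = 1e-12)
})

test_that("spectral features recover planted cycles and bound noise", {
  t <- (0:(25 * 30 - 1)) / 25
  # 5 Hz sine, exactly on a Fourier bin of the 1 s window
  f5 <- heaveSpectralFeatures(sin(2 * pi * 5 * t), 25)
  expect_equal(unique(f5$dominant_cycle_s), 0.2)
  expect_equal(mean(f5$cycle_amplitude_g), 1, tolerance = 0.01)

  # 0.3 s wingbeat cycle (3.33 Hz, off-bin): dominant cycle lands on the
  # nearest bin and the amplitude stays prominent despite leakage
  f3 <- heaveSpectralFeatures(sin(2 * pi * t / 0.3), 25)
  expect_true(all(f3$dominant_cycle_s >= 0.25 & f3$dominant_cycle_s <= 0.5))
  expect_gt(mean(f3$cycle_amplitude_g), 0.5)

  set.seed(3)
  fn <- heaveSpectralFeatures(rnorm(25 * 30, 0, 0.01), 25)
  expect_lt(max(fn$cycle_amplitude_g), 0.05)

  fc <- heaveSpectralFeatures(rep(1, 25 * 5), 25)
  expect_equal(max(fc$cycle_amplitude_g), 0, tolerance = 1e-12)
})

test_that("k-means separates planted flapping from quiet seconds", {
  set.seed(4)
  n <- 60
  feats <- data.frame(
    second = 0:(2 * n - 1),
    dominant_cycle_s = c(rnorm(n, 0.3, 0.01), runif(n, 0.1, 1)),
    cycle_amplitude_g = c(rnorm(n, 1, 0.05), rnorm(n, 0.05, 0.01)))
  flags <- clusterFlapping(feats, seed = 1)
  expect_equal(flags, rep(c(TRUE, FALSE), each = n))

  # permutation invariance of the assignment
  perm <- sample(2 * n)
  flagsP <- clusterFlapping(feats[perm, ], seed = 1)
  expect_equal(flagsP, flags[perm])

  same <- data.frame(second = 0:9, dominant_cycle_s = rep(0.3, 10),
                     cycle_amplitude_g = rep(0.5, 10))
  expect_warning(f0 <- clusterFlapping(same, seed = 1), "identical")
  expect_false(any(f0))
})

test_that("behaviour rules and smoothing behave as specified", {
  cfg <- analysisConfig()
  # all-flapping input stays all flap
  expect_equal(classifyBehaviour(rep(TRUE, 10), rep(0.4, 10), rep(1, 10),
                                 cfg),
               rep("flap", 10))
  # quiet + water-band static = raft; quiet + airborne static = glide
  lab <- classifyBehaviour(rep(FALSE, 12), rep(0.05, 12),
                           rep(c(0.85, 1), each = 6), cfg)
  expect_equal(lab, rep(c("raft", "glide"), each = 6))
  # single-second flicker is removed by the 3 s majority vote
  lab2 <- classifyBehaviour(c(FALSE, FALSE, TRUE, FALSE, FALSE),
                            rep(0.05, 5), rep(0.85, 5), cfg)
  expect_equal(lab2, rep("raft", 5))
  expect_error(classifyBehaviour(TRUE, 0.4, 1, list(tauWaterG = NULL)),
               "configuration error")
})

test_that("foraging detection applies the pitch rule on non-flying seconds", {
  cfg <- analysisConfig()
  labels <- c("raft", "flap", "raft", "glide")
  pitch <- c(-30, -30, -20, -40)
  f <- detectForaging(labels, pitch, cfg)
  expect_equal(f, c(TRUE, FALSE, FALSE, FALSE))
  # pressure-detected dive seconds are added unless the bird is flying
  f2 <- detectForaging(labels, pitch, cfg, diveSeconds = c(1L, 2L))
  expect_equal(f2, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("event segmentation merges at the 5 s gap and splits beyond it", {
  mk <- function(secs, n = 30) {
    f <- logical(n)
    f[secs + 1] <- TRUE
    f
  }
  ev <- segmentEvents(mk(c(10, 11, 12)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 3)

  expect_equal(nrow(segmentEvents(mk(c(10, 17)))), 2)  # gap 7 s splits
  expect_equal(nrow(segmentEvents(mk(c(10, 15)))), 1)  # gap 5 s merges
  expect_equal(nrow(segmentEvents(logical(10))), 0)

  # dive typing and location attachment
  dense <- data.frame(time = Sys.time() + 0:29, lat = seq(-42, -42.29, -0.01),
                      lon = rep(171, 30), elapsed_s = 0:29)
  ev2 <- segmentEvents(mk(c(5, 20)), denseTrack = dense,
                       diveSeconds = 20L)
  expect_equal(ev2$type, c("surface", "dive"))
  expect_equal(ev2$lat, dense$lat[c(6, 21)])
})

test_that("activity budget conserves time and foraging rate is arithmetic", {
  labels <- rep(c("flap", "raft", "glide"), times = c(50, 30, 20))
  forag <- labels == "raft" & seq_along(labels) %% 10 == 0
  b <- activityBudget(labels, forag)
  expect_equal(sum(b$proportionsPct), 100, tolerance = 1e-9)
  expect_equal(b$proportionsPct[["flap"]], 50)

  r <- foragingRate(10, 5)
  expect_equal(r$eventsPerH, 2)
  expect_true(is.na(foragingRate(0, 5)$kmPerEvent))
  # a 48 h, 780 km trip with 130 events: 2.708 events/h, 6 km per event
  r2 <- foragingRate(130, 48, 780)
  expect_equal(r2$eventsPerH, 2.7083, tolerance = 1e-4)
  expect_equal(r2$kmPerEvent, 6)
  expect_error(foragingRate(1, 0), "positive")
})

test_that("hourly profile of a uniform synthetic record is flat", {
  set.seed(7)
  n <- 48 * 3600
  labels <- sample(c("flap", "raft", "glide"), n, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
  b <- activityBudget(labels, logical(n),
                      startTime = as.POSIXct("2016-08-12", tz = "UTC"),
                      lon = 171)
  expect_equal(nrow(b$hourly), 24)
  expect_lt(max(abs(b$hourly$flap - 50)), 2)
})
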
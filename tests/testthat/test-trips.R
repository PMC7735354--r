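test_that("speed filter removes exactly the planted implausible fix", {
  # fixes 5 min apart moving 0.01 deg latitude (~1.1 km, ~3.7 m/s)
  trk <- lineTrack(10)
  expect_equal(fixes(filterSpeed(trk, 25)), fixes(trk))

  # plant one fix requiring ~30 m/s from its predecessor
  f <- fixes(trk)
  f$lat[5] <- f$lat[4] + 30 * 300 / 1000 / 111.1949  # 30 m/s for 300 s
  planted <- gpsTrack(f$time, f$lat, f$lon)
  filt <- filterSpeed(planted, 25)
  expect_equal(nrow(fixes(filt)), 9)
  expect_false(f$lat[5] %in% fixes(filt)$lat)

  # single fix passes through, idempotence holds
  one <- gpsTrack(f$time[1], f$lat[1], f$lon[1])
  expect_equal(fixes(filterSpeed(one, 25)), fixes(one))
  expect_equal(fixes(filterSpeed(filt, 25)), fixes(filt))
})

test_that("trips are cut at the colony radius", {
  cfg <- analysisConfig(colony = c(-42, 171), colonyRadiusKm = 1)
  t0 <- as.POSIXct("2016-08-12", tz = "UTC")
  # out (4 fixes), home (2), out (5), home (1)
  lat <- -42 + c(0, .1, .2, .3, .2, 0, 0, .1, .2, .3, .2, .1, 0)
  trk <- gpsTrack(t0 + 300 * seq_along(lat), lat, rep(171, length(lat)))
  trips <- segmentTrips(trk, cfg)
  expect_length(trips, 2)
  for (tr in trips) {
    f <- fixes(tr)
    d <- geosphere::distHaversine(cbind(f$lon, f$lat), c(171, -42),
                                  r = 6371000) / 1000
    # boundary fixes are inside the radius, interior fixes outside
    expect_lte(d[1], 1)
    expect_lte(d[length(d)], 1)
    expect_true(all(d[2:(length(d) - 1)] > 1))
  }

  home <- gpsTrack(t0 + 300 * (1:5), rep(-42.0001, 5), rep(171, 5))
  expect_message(expect_length(segmentTrips(home, cfg), 0), "never leaves")
})

test_that("trip metrics match hand-computed haversine values", {
  t0 <- as.POSIXct("2016-08-12", tz = "UTC")
  # two fixes one degree of latitude apart: 6371 * pi/180 = 111.1949 km
  trip <- new("Trip", fixes = data.frame(
    time = t0 + c(0, 3600, 7200),
    lat = c(-42, -43, -43), lon = c(171, 171, 171)),
    deploymentId = "d", tripId = 1L)
  m <- tripMetrics(trip, colony = c(-42, 171))
  expect_equal(m$total_distance_km, 111.1949, tolerance = 1e-4)
  expect_equal(m$max_distance_km, 111.1949, tolerance = 1e-4)
  expect_equal(m$duration_h, 2)
  expect_equal(m$mean_speed_kmh, m$total_distance_km / m$duration_h)

  # stationary trip: zero distance and speed
  still <- new("Trip", fixes = data.frame(
    time = t0 + c(0, 3600, 7200), lat = rep(-42, 3), lon = rep(171, 3)),
    deploymentId = "d", tripId = 1L)
  ms <- tripMetrics(still, colony = c(-42, 171))
  expect_equal(ms$total_distance_km, 0)
  expect_equal(ms$mean_speed_kmh, 0)

  zero <- new("Trip", fixes = data.frame(
    time = rep(t0, 3), lat = rep(-42, 3), lon = rep(171, 3)),
    deploymentId = "d", tripId = 1L)
  expect_error(suppressWarnings(tripMetrics(zero)), "zero-duration")
})

test_that("total distance equals an independent leg-sum oracle on random tracks", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    f <- data.frame(time = as.POSIXct("2016-08-12", tz = "UTC") + 300 * (1:n),
                    lat = -42 + cumsum(rnorm(n, 0, 0.05)),
                    lon = 171 + cumsum(rnorm(n, 0, 0.05)))
    trip <- new("Trip", fixes = f, deploymentId = "d", tripId = 1L)
    m <- tripMetrics(trip, colony = c(f$lat[1], f$lon[1]))
    oracle <- 0
    for (i in 2:n)
      oracle <- oracle + geosphere::distHaversine(
        c(f$lon[i - 1], f$lat[i - 1]), c(f$lon[i], f$lat[i]),
        r = 6371000) / 1000
    expect_equal(m$total_distance_km, oracle, tolerance = 1e-9)
  }
})

test_that("out-and-back trips obey the triangle bound on maximum range", {
  # for a path leaving and returning to the colony, reaching the farthest
  # point and coming home costs at least twice the maximum range
  set.seed(12)
  t0 <- as.POSIXct("2016-08-12", tz = "UTC")
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    out <- data.frame(lat = -42 + cumsum(rnorm(n, 0, 0.05)),
                      lon = 171 + cumsum(rnorm(n, 0, 0.05)))
    path <- rbind(data.frame(lat = -42, lon = 171), out,
                  out[rev(seq_len(n - 1)), ],
                  data.frame(lat = -42, lon = 171))
    trip <- new("Trip", fixes = cbind(time = t0 + 300 * seq_len(nrow(path)),
                                      path),
                deploymentId = "d", tripId = 1L)
    m <- tripMetrics(trip, colony = c(-42, 171))
    expect_lte(m$max_distance_km, m$total_distance_km / 2 + 1e-6)
  }
})

test_that("interpolation is linear, dense and endpoint-preserving", {
  t0 <- as.POSIXct("2016-08-12", tz = "UTC")
  trip <- new("Trip", fixes = data.frame(
    time = t0 + c(0, 100, 250), lat = c(-42, -42.1, -42.3),
    lon = c(171, 171.2, 171.1)), deploymentId = "d", tripId = 1L)
  d <- interpolateTrip(trip, 1)
  expect_equal(nrow(d), 251)  # floor(duration) + 1
  expect_equal(d$lat[1], -42)
  expect_equal(d$lat[251], -42.3)
  # midpoint of the first segment is the coordinate mean
  expect_equal(d$lat[51], mean(c(-42, -42.1)))
  expect_equal(d$lon[51], mean(c(171, 171.2)))
  # interpolated points stay inside the parents' bounding box
  expect_true(all(d$lat >= -42.3 - 1e-12 & d$lat <= -42 + 1e-12))
  expect_true(all(d$lon >= 171 - 1e-12 & d$lon <= 171.2 + 1e-12))
})

test_that("convex polygon area matches the spherical-zone closed form", {
  # 1 x 1 degree graticule square on the equator:
  # R^2 * dLambda * (sin 1 deg - sin 0) = 12363.9 km^2
  sq <- expand.grid(lat = seq(0, 1, by = 0.25), lon = seq(0, 1, by = 0.25))
  expect_equal(mcpArea(sq), 12364, tolerance = 5 / 12364)

  expect_error(mcpArea(data.frame(lat = rep(1, 5), lon = rep(2, 5))),
               "3 distinct")
  expect_error(mcpArea(data.frame(lat = c(0, 1, 2), lon = c(0, 1, 2))),
               "collinear")

  # permutation invariance and monotonicity under added points
  set.seed(3)
  pts <- data.frame(lat = runif(20, -1, 1), lon = runif(20, 170, 172))
  a1 <- mcpArea(pts)
  a2 <- mcpArea(pts[sample(nrow(pts)), ])
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_gte(mcpArea(rbind(pts, data.frame(lat = 2, lon = 173))), a1)
})

test_that("bimodality coefficient hits its analytic benchmarks", {
  set.seed(5)
  expect_equal(bimodalityCoefficient(runif(50000)), 5 / 9, tolerance = 0.03)
  expect_equal(bimodalityCoefficient(rnorm(50000)), 1 / 3, tolerance = 0.03)
  # well-separated mixture flags bimodality
  mix <- c(rnorm(100, 24, 6), rnorm(100, 240, 24))
  expect_gt(bimodalityCoefficient(mix), 5 / 9)
  # n = 4 edge case is finite and in range
  bc4 <- bimodalityCoefficient(c(1, 2, 3, 10))
  expect_true(is.finite(bc4) && bc4 > 0 && bc4 <= 1)
  expect_error(bimodalityCoefficient(c(1, 2, 3)), "n >= 4")
})

test_that("mixture mode estimation recovers one and two modes", {
  set.seed(6)
  uni <- rnorm(200, 72, 10)
  m1 <- estimateModes(uni)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$location, 72, tolerance = 3 / 72)

  bi <- c(rnorm(100, 24, 6), rnorm(100, 240, 24))
  m2 <- estimateModes(bi)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$location[1], 24, tolerance = 3 / 24)
  expect_equal(m2$location[2], 240, tolerance = 9 / 240)

  cst <- estimateModes(rep(7, 20))
  expect_equal(cst, data.frame(location = 7, weight = 1))

  ms <- modalityStats(bi)
  expect_true(ms$flagBimodal)
})
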
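test_that("pressure-to-depth follows D = 0.01 (Pm - Pa)", {
  expect_equal(pressureToDepth(1013, 1013), 0)
  expect_equal(pressureToDepth(1113, 1013), 1)
  expect_equal(pressureToDepth(1068, 1013), 0.55)
  expect_equal(pressureToDepth(c(1000, 1010), 1013), c(-0.13, -0.03))
  expect_error(pressureToDepth(1000, 0), "positive")
})

test_that("surface drift correction re-anchors the surface at zero", {
  # linear drift of +0.5 m over 1 h with no dives
  drift <- seq(0, 0.5, length.out = 3600)
  corr <- correctSurfaceDrift(drift)
  expect_lt(max(abs(corr)), 0.1)

  # constant offset is removed exactly
  corr2 <- correctSurfaceDrift(rep(0.3, 1200))
  expect_equal(corr2, rep(0, 1200))

  # a 2 m dive on a flat baseline is preserved
  depth <- rep(0, 1800)
  depth[900:904] <- c(1, 2, 2, 1, 0.2)
  corr3 <- correctSurfaceDrift(depth)
  expect_equal(max(corr3), 2, tolerance = 0.05 / 2)

  # window longer than the series: single global baseline
  expect_equal(correctSurfaceDrift(rep(0.2, 30), windowS = 600),
               rep(0, 30))
})

test_that("dive detection applies the strict 0.55 m rule and V geometry", {
  # excursion peaking at 0.5 m is not a dive; 0.55 m exactly is not either
  expect_equal(nrow(detectDives(c(0, 0.3, 0.5, 0.3, 0))), 0)
  expect_equal(nrow(detectDives(c(0, 0.55, 0))), 0)

  # V-excursion 0 -> 2.1 m -> 0 over 5 s, apex at 2.5 s: sampled at 1 Hz the
  # deepest sample lies on the descent leg, so the rate is 2.1/2.5 = 0.84
  v <- c(0, 0.84, 1.68, 1.68, 0.84, 0)
  d <- detectDives(v)
  expect_equal(nrow(d), 1)
  expect_equal(d$max_depth_m, 1.68)
  expect_equal(d$descent_rate_ms, 0.84)

  # two excursions separated by a surface sample stay distinct
  two <- c(0, 1, 2, 1, 0, 1.5, 0.8, 0)
  expect_equal(nrow(detectDives(two)), 2)

  # dive count is monotone non-increasing in the threshold
  set.seed(8)
  tr <- simulateDiveTrace(15, seed = 8)
  depth <- correctSurfaceDrift(pressureToDepth(tr$pressure, tr$atmospheric))
  counts <- vapply(c(0.3, 0.55, 1, 2), function(th)
    nrow(detectDives(depth, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fleet descent rate recovers the simulated rate", {
  # noise-free exact rate
  exact <- data.frame(max_depth_m = c(1.68, 2.52, 0.84),
                      descent_duration_s = c(2, 3, 1))
  expect_equal(fleetDescentRate(exact)$rateMs, 0.84)

  # quantized 5 mBar sensor, 30 dives
  tr <- simulateDiveTrace(30, seed = 9)
  depth <- correctSurfaceDrift(pressureToDepth(tr$pressure, tr$atmospheric))
  dives <- detectDives(depth)
  est <- fleetDescentRate(dives)
  expect_equal(est$rateMs, 0.84, tolerance = 0.05)
  # heterogeneous rates: the fleet estimate lies between the extremes
  het <- data.frame(max_depth_m = c(1, 3, 5), descent_duration_s = c(2, 3, 4))
  fr <- fleetDescentRate(het)
  expect_gte(fr$rateMs, min(fr$perDiveRates))
  expect_lte(fr$rateMs, max(fr$perDiveRates))
  expect_error(fleetDescentRate(exact[1:2, ]), "at least 3")
})

test_that("depth-from-duration halves the V and matches the field pair", {
  # mean dive of 3.1 s at 0.84 m/s descends half the time: 1.3 m
  expect_equal(round(depthFromDuration(3.1, 0.84), 1), 1.3)
  expect_equal(depthFromDuration(0, 0.84), 0)
  expect_equal(depthFromDuration(26, 0.84), 10.92)
  expect_error(depthFromDuration(-1, 0.84), "non-negative")
  expect_error(depthFromDuration(1, 0), "positive")
})

test_that("cross-sensor validation scores overlap correctly", {
  dives <- data.frame(start_s = seq(0, 90, by = 10),
                      end_s = seq(3, 93, by = 10))
  # identical lists: 100%
  expect_equal(validateDetection(dives, dives), 100)
  # drop one accel event: 9/10 = 90%
  expect_equal(validateDetection(dives[-4, ], dives), 90)
  expect_true(is.na(validateDetection(dives, dives[0, ])))
  expect_equal(validateDetection(dives[0, ], dives), 0)
  # the +/- 2 s window forgives small offsets
  shifted <- transform(dives, start_s = start_s + 2, end_s = end_s + 2)
  expect_equal(validateDetection(shifted, dives), 100)
})

test_that("simulated pressure inverts back to the planted dive profile", {
  tr <- simulateDiveTrace(12, seed = 10)
  depth <- correctSurfaceDrift(pressureToDepth(tr$pressure, tr$atmospheric))
  dives <- detectDives(depth)
  expect_equal(nrow(dives), 12)
  # apex depths match the planted dives within sensor resolution (0.05 m)
  expect_equal(dives$max_depth_m, tr$dives$max_depth_m, tolerance = 0.08)
  expect_equal(dives$duration_s, tr$dives$duration_s, tolerance = 0.2)
})
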
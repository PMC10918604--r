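test_that("null flow keeps every particle at its release point", {
  f <- uniformField(0, 0)
  rel <- releaseSpec("A", 2, 0, nParticles = 25, duration = 14, scatterKm = 0)
  ts <- advect(f, rel)
  fin <- snapshotPositions(ts, 14)
  expect_equal(fin$lon, rep(2, 25))
  expect_equal(fin$lat, rep(0, 25))
  expect_equal(sum(!is.na(deathTimes(ts))), 0)
})

test_that("uniform eastward drift covers the closed-form distance", {
  f <- uniformField(0.1, 0)
  rel <- releaseSpec("A", 0.5, 0, nParticles = 5, duration = 14, scatterKm = 0)
  ts <- advect(f, rel)
  fin <- snapshotPositions(ts, 14)
  d <- haversineKm(0.5, 0, fin$lon, fin$lat)
  expect_equal(mean(d), 120.96, tolerance = 0.01)
})

test_that("flow into a coast kills particles at the distance/speed time", {
  land <- matrix(FALSE, 201, 41)
  land[1:20, ] <- TRUE   # land on the west
  f <- uniformField(-0.1, 0, lonMin = 0, lonMax = 2, latMin = -0.2,
                    latMax = 0.2, dGrid = 0.01, land = land)
  edge <- (f@lon[20] + f@lon[21]) / 2   # nearest-cell land boundary
  startLon <- edge + 10 / 111.32        # 10 km east of the boundary
  rel <- releaseSpec("A", startLon, 0, nParticles = 10, duration = 5,
                     scatterKm = 0)
  ts <- advect(f, rel, stepMinutes = 15)
  dt <- deathTimes(ts)
  expect_true(all(!is.na(dt)))
  expected <- 10 / (0.1 * 86.4)         # km / (km/day)
  expect_equal(mean(dt), expected, tolerance = 0.15)
})

test_that("a solid-body rotation closes its orbit within 1 km", {
  period <- 2                                  # days
  f <- rotationField(period, half = 1, days = 6)
  rel <- releaseSpec("A", 0.45, 0, nParticles = 3, duration = period,
                     scatterKm = 0)
  ts <- advect(f, rel, stepMinutes = 15)
  fin <- snapshotPositions(ts, period)
  gap <- haversineKm(0.45, 0, fin$lon, fin$lat)
  expect_lt(max(gap), 1)
})

test_that("halving the step moves 21-day endpoints by < 0.5 km", {
  spec <- syntheticOceanSpec(seed = 21, landRects = list(),
                             jetSpeed = 0.05, eddyAmp = 0.15)
  f <- makeVelocityField(spec, "2010")
  rel <- releaseSpec("A", -9, 43, nParticles = 8, duration = 21, scatterKm = 1)
  a <- snapshotPositions(advect(f, rel, stepMinutes = 60), 21)
  b <- snapshotPositions(advect(f, rel, stepMinutes = 30), 21)
  expect_lt(max(haversineKm(a$lon, a$lat, b$lon, b$lat)), 0.5)
})

test_that("particle counts are conserved at every snapshot", {
  spec <- syntheticOceanSpec(seed = 8, jetSpeed = 0.2, eddyAmp = 0.3)
  f <- makeVelocityField(spec, "2010")
  rel <- releaseSpec("A", -7.8, 42, nParticles = 60, duration = 14)
  ts <- advect(f, rel)
  for (day in ts@times) {
    snap <- snapshotPositions(ts, day)
    expect_equal(sum(snap$alive) + sum(!snap$alive), 60)
    expect_equal(sum(!snap$alive),
                 sum(!is.na(deathTimes(ts)) & deathTimes(ts) <= day + 1e-9))
  }
})

test_that("advecting back through the negated field returns to the start", {
  spec <- syntheticOceanSpec(seed = 13, landRects = list(), eddyAmp = 0.15,
                             jetSpeed = 0.05)
  f <- makeVelocityField(spec, "2010")
  rel <- releaseSpec("A", -9, 43, nParticles = 6, duration = 7, scatterKm = 1)
  ts <- advect(f, rel, stepMinutes = 15)
  fin <- snapshotPositions(ts, 7)
  fb <- negateField(f)
  back <- vapply(seq_len(6), function(i) {
    r <- releaseSpec("B", fin$lon[i], fin$lat[i], nParticles = 1,
                     duration = 7, scatterKm = 0)
    p <- snapshotPositions(advect(fb, r, stepMinutes = 15), 7)
    haversineKm(p$lon, p$lat, ts@lon[i, 1], ts@lat[i, 1])
  }, numeric(1))
  expect_lt(max(back), 1)
})

test_that("invalid releases are rejected", {
  land <- matrix(FALSE, 41, 41)
  land[30:41, ] <- TRUE
  f <- uniformField(0.1, 0, dGrid = 0.1, land = land)
  expect_error(advect(f, releaseSpec("A", f@lon[35], 0, 10)), "land")
  expect_error(advect(f, releaseSpec("A", 1, 0, 10), stepMinutes = 0), "step")
  expect_error(releaseSpec("A", 1, 0, nParticles = 0))
})

test_that("campaigns produce one trajectory set per site-year with windows", {
  f <- uniformField(0.02, 0, days = 30)
  sites <- data.frame(site = c("A", "B"), lon = c(1, 2), lat = c(0, 0.5))
  fields <- list("2010" = f, "2011" = f, "2012" = f)
  tr <- runCampaign(fields, sites, c("2010", "2011", "2012"),
                    config = list(nParticles = 5, duration = 21,
                                  startDay = 7.5,
                                  groups = list(list(sites = "A",
                                                     startDay = 0.5))))
  expect_length(tr, 6)
  expect_equal(tr[["A_2010"]]@release$start, 0.5)
  expect_equal(tr[["B_2010"]]@release$start - tr[["A_2010"]]@release$start, 7)

  expect_warning(out <- runCampaign(fields, sites, character(0)), "no years")
  expect_length(out, 0)
  expect_warning(tr2 <- runCampaign(fields["2010"], sites, c("2010", "2013"),
                                    config = list(nParticles = 2, duration = 21)),
                 "2013")
  expect_length(tr2, 2)
})
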
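test_that("zero flow yields the identity connectivity matrix", {
  f <- uniformField(0, 0)
  sites <- data.frame(site = c("A", "B", "C"), lon = c(0.5, 2, 3.5),
                      lat = c(0, 0, 0))
  tr <- runCampaign(list("2010" = f), sites, "2010",
                    config = list(nParticles = 20, duration = 14,
                                  scatterKm = 0.5))
  P <- connMean(dispersalMatrix(tr, sites, 14))
  expect_equal(P, diag(3), ignore_attr = TRUE)
})

test_that("a hand-built release reproduces the 4/9 worked example", {
  # 10 particles from A: 1 dead, 4 of the 9 survivors in B's zone at day 14
  times <- c(0, 14)
  sites <- data.frame(site = c("A", "B"), lon = c(0, 1), lat = c(0, 0))
  pos <- list()
  for (k in 1:4) pos[[k]] <- rbind(c(0, 0), c(1.05, 0))     # inside B (~6 km)
  for (k in 5:9) pos[[k]] <- rbind(c(0, 0), c(0.5, 1.5))    # far from both
  pos[[10]] <- rbind(c(0, 0), c(NA, NA))                    # dead
  ts <- manualTrajectories(pos, times, c(rep(NA, 9), 3), site = "A",
                           relLon = 0, relLat = 0)
  P <- connMean(dispersalMatrix(list(ts), sites, 14, radiusKm = 20))
  expect_equal(P["A", "B"], 4 / 9, tolerance = 1e-12)
  expect_equal(P["A", "A"], 0)
})

test_that("radius zero degenerates to coincidences and radius is monotone", {
  f <- uniformField(0.03, 0.01)
  sites <- data.frame(site = c("A", "B"), lon = c(0.6, 1.2), lat = c(0, 0.2))
  tr <- runCampaign(list("2010" = f), sites, "2010",
                    config = list(nParticles = 25, duration = 14))
  p0 <- connMean(dispersalMatrix(tr, sites, 14, radiusKm = 0))
  expect_true(all(p0[upper.tri(p0) | lower.tri(p0)] == 0))
  radii <- c(5, 10, 20, 50, 100)
  prev <- matrix(0, 2, 2)
  for (r in radii) {
    P <- connMean(dispersalMatrix(tr, sites, 14, radiusKm = r))
    expect_true(all(P >= prev - 1e-12))
    prev <- P
  }
})

test_that("any-time-entry membership dominates the snapshot convention", {
  spec <- syntheticOceanSpec(seed = 14, landRects = list(),
                             jetSpeed = 0.06, eddyAmp = 0.1)
  f <- makeVelocityField(spec, "2010")
  sites <- data.frame(site = c("A", "B"), lon = c(-9.5, -9), lat = c(42, 42.6))
  tr <- runCampaign(list("2010" = f), sites, "2010",
                    config = list(nParticles = 40, duration = 14))
  Ps <- connMean(dispersalMatrix(tr, sites, 14, convention = "snapshot"))
  Pa <- connMean(dispersalMatrix(tr, sites, 14, convention = "any_time"))
  expect_true(all(Pa >= Ps - 1e-12))
})

test_that("connectivity follows the alongshore jet direction", {
  # northward 0.04 m/s carries particles ~48 km in 14 days; sites 40 km apart
  f <- uniformField(0, 0.04, lonMin = 0, lonMax = 4, latMin = -0.5,
                    latMax = 2.5)
  sites <- data.frame(site = c("A", "B", "C", "D"), lon = rep(2, 4),
                      lat = c(0, 0.36, 0.72, 1.08))
  tr <- runCampaign(list("2010" = f), sites, "2010",
                    config = list(nParticles = 40, duration = 14))
  P <- connMean(dispersalMatrix(tr, sites, 14))
  down <- sum(P[upper.tri(P)], na.rm = TRUE)   # northward = increasing index
  up <- sum(P[lower.tri(P)], na.rm = TRUE)
  expect_gt(down, up)
})

test_that("dispersal summaries match hand-computed displacements", {
  sites <- data.frame(site = "A", lon = 0, lat = 0)
  # three survivors at fixed haversine distances 1, 2 and 6 km
  dKm <- c(1, 2, 6)
  lons <- dKm / 111.32
  pos <- lapply(lons, function(x) rbind(c(0, 0), c(x, 0)))
  ts <- manualTrajectories(pos, c(0, 14), rep(NA_real_, 3),
                           relLon = 0, relLat = 0)
  sm <- dispersalSummary(list(ts), sites, 14)
  expect_equal(sm$meanDispKm, 3, tolerance = 1e-3)
  expect_equal(sm$maxDispKm, 6, tolerance = 1e-3)
  expect_equal(sm$pctRemaining, 100)
  expect_named(sm, c("site", "pld", "pctRemaining", "pctSourceZone",
                     "meanDispKm", "maxDispKm"))

  # static particles: zero displacement, full retention
  f <- uniformField(0, 0)
  sitesB <- data.frame(site = "B", lon = 2, lat = 0)
  tr <- runCampaign(list("2010" = f), sitesB, "2010",
                    config = list(nParticles = 10, duration = 14,
                                  scatterKm = 0))
  smB <- dispersalSummary(tr, sitesB, 14)
  expect_equal(smB$meanDispKm, 0)
  expect_equal(smB$maxDispKm, 0)
  expect_equal(smB$pctSourceZone, 100)
})

test_that("interannual report flags constructed rare years only", {
  f <- uniformField(0.02, 0)
  sites <- data.frame(site = "A", lon = 0.5, lat = 0)
  identical3 <- runCampaign(list("2010" = f, "2011" = f, "2012" = f), sites,
                            c("2010", "2011", "2012"),
                            config = list(nParticles = 10, duration = 14))
  rep0 <- interannualReport(identical3, sites, 14)
  expect_equal(rep0$perSite$rangeMeanKm, 0, tolerance = 1e-9)
  expect_gte(rep0$perSite$ratioMaxMean, 1)
  expect_equal(nrow(rep0$flagged), 0)

  fBig <- uniformField(0.06, 0)    # 3x advection year
  mixed <- runCampaign(list("2010" = f, "2011" = f, "2012" = fBig), sites,
                       c("2010", "2011", "2012"),
                       config = list(nParticles = 10, duration = 14))
  rep1 <- interannualReport(mixed, sites, 14, factor = 2)
  expect_equal(rep1$flagged$year, "2012")

  rep2 <- interannualReport(identical3[1], sites, 14)
  expect_true(is.na(rep2$perSite$rangeMeanKm))
  expect_false(is.null(rep2$note))
})
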
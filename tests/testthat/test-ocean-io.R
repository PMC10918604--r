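test_that("NetCDF write/read round-trips fields exactly, flipping axes", {
  spec <- syntheticOceanSpec(seed = 9, dLon = 0.2, dLat = 0.2, days = 4)
  f <- makeVelocityField(spec, "2010")
  tf <- tempfile(fileext = ".nc")
  writeVelocityField(f, tf)
  fr <- readVelocityField(tf)
  expect_identical(fr@lon, f@lon)
  expect_equal(fr@u, f@u)
  expect_equal(fr@v, f@v)
  expect_identical(fr@land, f@land)

  # store latitude descending, expect ascending return with rows flipped
  nc <- ncdf4::nc_open(tf)
  u <- ncdf4::ncvar_get(nc, "uo", collapse_degen = FALSE)
  v <- ncdf4::ncvar_get(nc, "vo", collapse_degen = FALSE)
  lon <- ncdf4::ncvar_get(nc, "longitude")
  lat <- ncdf4::ncvar_get(nc, "latitude")
  tt <- ncdf4::ncvar_get(nc, "time")
  ncdf4::nc_close(nc)
  tf2 <- tempfile(fileext = ".nc")
  dl <- ncdf4::ncdim_def("longitude", "degrees_east", lon)
  dlat <- ncdf4::ncdim_def("latitude", "degrees_north", rev(lat))
  dt <- ncdf4::ncdim_def("time", "days", tt)
  fill <- 9.96921e36
  vu <- ncdf4::ncvar_def("uo", "m s-1", list(dl, dlat, dt), fill, prec = "double")
  vv <- ncdf4::ncvar_def("vo", "m s-1", list(dl, dlat, dt), fill, prec = "double")
  nc2 <- ncdf4::nc_create(tf2, list(vu, vv))
  rev2 <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  uD <- rev2(u); uD[is.na(uD)] <- fill
  vD <- rev2(v); vD[is.na(vD)] <- fill
  ncdf4::ncvar_put(nc2, vu, uD)
  ncdf4::ncvar_put(nc2, vv, vD)
  ncdf4::nc_close(nc2)
  fr2 <- readVelocityField(tf2)
  expect_equal(fr2@lat, f@lat)
  expect_equal(fr2@u, f@u)
})

test_that("a missing velocity variable is reported by name", {
  spec <- syntheticOceanSpec(seed = 9, dLon = 0.5, dLat = 0.5, days = 2)
  f <- makeVelocityField(spec, "2010")
  tf <- tempfile(fileext = ".nc")
  writeVelocityField(f, tf)
  expect_error(readVelocityField(tf, varNames = list(
    u = "uo", v = "northward_velocity", lon = "longitude",
    lat = "latitude", time = "time")), "northward_velocity")
})

test_that("interpolation is exact at nodes, linear between, and matches a
           brute-force oracle at interior points", {
  f <- uniformField(0.1, 0.05)
  # overwrite one column to create a gradient in u
  f@u[10, , ] <- 0.3
  s <- sampleVelocity(f, f@lon[10], f@lat[5], 3)
  expect_equal(s$u, 0.3, tolerance = 1e-12)
  mid <- sampleVelocity(f, (f@lon[10] + f@lon[11]) / 2, f@lat[5], 3)
  expect_equal(mid$u, 0.2, tolerance = 1e-12)

  spec <- syntheticOceanSpec(seed = 3)
  g <- makeVelocityField(spec, "2010")
  set.seed(41)
  for (k in 1:20) {
    x <- runif(1, min(g@lon), max(g@lon))
    y <- runif(1, min(g@lat), max(g@lat))
    t <- runif(1, 0, max(g@time))
    got <- sampleVelocity(g, x, y, t)
    want <- oracleSampleVelocity(g, x, y, t)
    expect_equal(c(got$u, got$v), want, tolerance = 1e-12)
  }
})

test_that("land neighbours contribute zero with renormalized weights", {
  land <- matrix(FALSE, 41, 41)
  land[21, ] <- TRUE                       # land column
  f <- uniformField(0.2, 0, dGrid = 0.1, land = land)
  # query next to the land column: only ocean neighbours used
  x <- f@lon[20] + 0.05
  s <- sampleVelocity(f, x, f@lat[10], 2)
  expect_equal(s$u, 0.2, tolerance = 1e-12)
  # all-land neighbourhood signals on-land as NA, distinct from the
  # out-of-domain error
  land2 <- matrix(TRUE, 41, 41)
  land2[1:5, ] <- FALSE
  f2 <- uniformField(0.2, 0, dGrid = 0.1, land = land2)
  sOn <- sampleVelocity(f2, f2@lon[30], f2@lat[10], 2)
  expect_true(is.na(sOn$u))
  expect_error(sampleVelocity(f2, max(f2@lon) + 1, f2@lat[10], 2), "domain")
  expect_error(sampleVelocity(f2, f2@lon[3], f2@lat[3], 99), "time")
})

test_that("isLand uses nearest-cell semantics with an east/north tie-break", {
  land <- matrix(FALSE, 11, 11)
  land[6, ] <- TRUE
  f <- uniformField(0, 0, lonMin = 0, lonMax = 1, latMin = 0, latMax = 1,
                    dGrid = 0.1, land = land)
  expect_true(isLand(f, f@lon[6], f@lat[3]))
  expect_false(isLand(f, f@lon[5], f@lat[3]))
  # exact midpoint rounds towards the higher-index (eastern) cell
  expect_true(isLand(f, (f@lon[5] + f@lon[6]) / 2, f@lat[3]))
  expect_false(isLand(f, (f@lon[6] + f@lon[7]) / 2, f@lat[3]))
  expect_error(isLand(f, 2, 0.5), "domain")
})
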
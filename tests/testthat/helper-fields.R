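# hand-built velocity fields for tracker/interpolation tests

# constant-velocity field on a lon/lat grid, no land unless a mask is given
uniformField <- function(u, v, lonMin = 0, lonMax = 4, latMin = -2, latMax = 2,
                         dGrid = 0.1, days = 22, land = NULL) {
  lon <- seq(lonMin, lonMax, by = dGrid)
  lat <- seq(latMin, latMax, by = dGrid)
  tt <- seq(0, days, by = 1)
  if (is.null(land)) land <- matrix(FALSE, length(lon), length(lat))
  u3 <- array(u, dim = c(length(lon), length(lat), length(tt)))
  v3 <- array(v, dim = c(length(lon), length(lat), length(tt)))
  u3[rep(land, length(tt))] <- NA_real_
  v3[rep(land, length(tt))] <- NA_real_
  new("VelocityField", lon = lon, lat = lat, time = tt,
      u = u3, v = v3, land = land)
}

# solid-body rotation about (0, 0) with the given period in days;
# u, v linear in lat/lon so bilinear interpolation is exact
rotationField <- function(period, half = 1, dGrid = 0.02, days = 22) {
  lon <- seq(-half, half, by = dGrid)
  lat <- seq(-half, half, by = dGrid)
  tt <- seq(0, days, by = 1)
  omega <- 2 * pi / period                  # phase rate, rad/day
  # deg/day -> m/s conversion consistent with the tracker's local metric
  k <- 111.32 / 86.4
  uG <- outer(lon, lat, function(x, y) -omega * y * k)
  vG <- outer(lon, lat, function(x, y) omega * x * k)
  u3 <- array(rep(uG, length(tt)), dim = c(length(lon), length(lat), length(tt)))
  v3 <- array(rep(vG, length(tt)), dim = c(length(lon), length(lat), length(tt)))
  new("VelocityField", lon = lon, lat = lat, time = tt, u = u3, v = v3,
      land = matrix(FALSE, length(lon), length(lat)))
}

# negate a (time-constant) field for reversibility checks
negateField <- function(f) {
  new("VelocityField", lon = f@lon, lat = f@lat, time = f@time,
      u = -f@u, v = -f@v, land = f@land)
}

# TrajectorySet built directly from prescribed positions; positions is a
# list of particle matrices [snapshot, 2]; dead particles padded with NA
manualTrajectories <- function(positions, times, deathTime, site = "A",
                               relLon, relLat, year = "2010") {
  n <- length(positions)
  lonM <- t(vapply(positions, function(m) m[, 1], numeric(length(times))))
  latM <- t(vapply(positions, function(m) m[, 2], numeric(length(times))))
  new("TrajectorySet", lon = lonM, lat = latM, times = times,
      deathTime = deathTime,
      release = list(site = site, lon = relLon, lat = relLat, year = year,
                     nParticles = n, start = 0.5, duration = max(times)))
}
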
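#' Release specification for one site-year
#'
#' @param site site name.
#' @param lon,lat release coordinates (degrees); must be an ocean point.
#' @param nParticles number of particles (> 0).
#' @param start release time in days on the field clock (default 0.5: noon
#'   of day 1).
#' @param duration drift duration in days (> 0).
#' @param year year label.
#' @param scatterKm radius of the uniform release disc (km); 0 = point
#'   release.
#' @param seed integer seed for the release scatter.
#' @return a \code{ReleaseSpec} (list).
#' @export
releaseSpec <- function(site, lon, lat, nParticles = 5000L, start = 0.5,
                        duration = 21, year = "2010", scatterKm = 1,
                        seed = 1L) {
  stopifnot(nParticles > 0, duration > 0, scatterKm >= 0)
  structure(list(site = site, lon = lon, lat = lat,
                 nParticles = as.integer(nParticles), start = start,
                 duration = duration, year = as.character(year),
                 scatterKm = scatterKm, seed = as.integer(seed)),
            class = "ReleaseSpec")
}

# velocity in degrees/day with out-of-domain and on-land queries mapped to
# zero velocity; the post-step position check decides life and death
.velDegPerDay <- function(field, lon, lat, t) {
  gx <- field@lon; gy <- field@lat
  lonC <- pmin(pmax(lon, gx[1]), gx[length(gx)])
  latC <- pmin(pmax(lat, gy[1]), gy[length(gy)])
  s <- sampleVelocity(field, lonC, latC, t)
  u <- s$u; v <- s$v
  u[is.na(u)] <- 0; v[is.na(v)] <- 0
  out <- lon != lonC | lat != latC
  u[out] <- 0; v[out] <- 0
  list(dlon = .uToDegPerDay(u, latC), dlat = .vToDegPerDay(v))
}

#' Advect passive particles through a velocity field
#'
#' Positions are advanced with 4th-order Runge-Kutta on the interpolated
#' velocities. A step that ends on a land cell, or outside the grid domain,
#' kills the particle at that step; dead particles carry \code{NA} positions
#' from the following snapshot on. Snapshots are stored at release and at
#' every whole day up to \code{release$duration} (which always includes the
#' 14- and 21-day marks when the duration covers them).
#'
#' @param field a \linkS4class{VelocityField}.
#' @param release a \code{\link{releaseSpec}}.
#' @param stepMinutes integration step in minutes (> 0). Internally rounded
#'   so that a whole number of steps spans one day.
#' @return a \linkS4class{TrajectorySet}.
#' @export
advect <- function(field, release, stepMinutes = 60) {
  stopifnot(inherits(release, "ReleaseSpec"))
  if (stepMinutes <= 0) stop("stepMinutes must be > 0")
  if (isLand(field, release$lon, release$lat))
    stop("release point is on land: ", release$site)
  tEnd <- release$start + release$duration
  tSpan <- range(timeAxis(field))
  if (release$start < tSpan[1] - 1e-9 || tEnd > tSpan[2] + 1e-9)
    stop("release window [", release$start, ", ", tEnd,
         "] not covered by field time span")

  n <- release$nParticles
  # scatter depends on site and seed only, so identical fields in different
  # years give identical trajectories (interannual variation comes from the
  # ocean, not the release draw)
  restoreRng <- .localSeed(.subSeed(release$seed, release$site, "scatter"))
  on.exit(restoreRng(), add = TRUE)
  if (release$scatterKm > 0) {
    r <- release$scatterKm * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    lon <- release$lon + r * cos(th) / (.KM_PER_DEG * cos(release$lat * pi / 180))
    lat <- release$lat + r * sin(th) / .KM_PER_DEG
    # scatter positions falling on land or outside the grid collapse back
    # to the release point
    gx <- range(field@lon); gy <- range(field@lat)
    bad <- lon < gx[1] | lon > gx[2] | lat < gy[1] | lat > gy[2]
    bad[!bad] <- isLand(field, lon[!bad], lat[!bad])
    lon[bad] <- release$lon; lat[bad] <- release$lat
  } else {
    lon <- rep(release$lon, n); lat <- rep(release$lat, n)
  }

  stepsPerDay <- max(1L, as.integer(ceiling(1440 / stepMinutes)))
  dt <- 1 / stepsPerDay
  nDays <- as.integer(ceiling(release$duration - 1e-9))
  snapTimes <- 0:nDays
  snapLon <- matrix(NA_real_, n, nDays + 1L)
  snapLat <- matrix(NA_real_, n, nDays + 1L)
  snapLon[, 1] <- lon; snapLat[, 1] <- lat
  alive <- rep(TRUE, n)
  deathTime <- rep(NA_real_, n)
  gx <- range(field@lon); gy <- range(field@lat)

  for (day in seq_len(nDays)) {
    for (s in seq_len(stepsPerDay)) {
      if (!any(alive)) break
      t0 <- release$start + (day - 1) + (s - 1) * dt
      ii <- which(alive)
      x <- lon[ii]; y <- lat[ii]
      k1 <- .velDegPerDay(field, x, y, t0)
      k2 <- .velDegPerDay(field, x + dt / 2 * k1$dlon, y + dt / 2 * k1$dlat, t0 + dt / 2)
      k3 <- .velDegPerDay(field, x + dt / 2 * k2$dlon, y + dt / 2 * k2$dlat, t0 + dt / 2)
      k4 <- .velDegPerDay(field, x + dt * k3$dlon, y + dt * k3$dlat, t0 + dt)
      xn <- x + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
      yn <- y + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
      out <- xn < gx[1] | xn > gx[2] | yn < gy[1] | yn > gy[2]
      dead <- out
      if (any(!out)) dead[!out] <- isLand(field, xn[!out], yn[!out])
      tNow <- (day - 1) + s * dt
      if (any(dead)) {
        alive[ii[dead]] <- FALSE
        deathTime[ii[dead]] <- tNow
      }
      keep <- !dead
      lon[ii[keep]] <- xn[keep]
      lat[ii[keep]] <- yn[keep]
    }
    snapLon[alive, day + 1L] <- lon[alive]
    snapLat[alive, day + 1L] <- lat[alive]
  }

  new("TrajectorySet", lon = snapLon, lat = snapLat, times = snapTimes,
      deathTime = deathTime,
      release = unclass(release))
}

#' Run a multi-site, multi-year tracking campaign
#'
#' One \linkS4class{TrajectorySet} per site-year. Site groups may be mapped
#' to staggered release windows via \code{config$groups}; site-years without
#' field coverage are skipped with a warning, not an error.
#'
#' @param fieldForYear a function \code{year -> VelocityField}, or a named
#'   list of fields keyed by year label; missing/failing years are skipped.
#' @param sites site table (\code{site, lon, lat, ...}).
#' @param years vector of year labels.
#' @param config list: \code{nParticles} (default 5000), \code{stepMinutes}
#'   (60), \code{duration} days (21), \code{startDay} (0.5), \code{scatterKm}
#'   (1), \code{seed} (1), and optionally \code{groups}, a list of
#'   \code{list(sites =, startDay =)} entries mapping site groups to
#'   staggered windows.
#' @return named list of \linkS4class{TrajectorySet} keyed \code{site_year}.
#' @export
runCampaign <- function(fieldForYear, sites, years, config = list()) {
  cfg <- utils::modifyList(list(nParticles = 5000L, stepMinutes = 60,
                                duration = 21, startDay = 0.5,
                                scatterKm = 1, seed = 1L, groups = NULL),
                           config)
  if (length(years) == 0L) {
    warning("no years supplied; empty campaign")
    return(list())
  }
  getField <- if (is.function(fieldForYear)) fieldForYear else
    function(y) fieldForYear[[as.character(y)]]
  startFor <- function(site) {
    if (!is.null(cfg$groups)) {
      for (gr in cfg$groups) if (site %in% gr$sites) return(gr$startDay)
    }
    cfg$startDay
  }
  out <- list()
  for (y in years) {
    fld <- tryCatch(getField(y), error = function(e) NULL)
    if (is.null(fld)) {
      warning("no velocity field for year ", y, "; skipped")
      next
    }
    for (i in seq_len(nrow(sites))) {
      rel <- releaseSpec(sites$site[i], sites$lon[i], sites$lat[i],
                         nParticles = cfg$nParticles,
                         start = startFor(sites$site[i]),
                         duration = cfg$duration, year = y,
                         scatterKm = cfg$scatterKm, seed = cfg$seed)
      out[[paste0(sites$site[i], "_", y)]] <-
        advect(fld, rel, stepMinutes = cfg$stepMinutes)
    }
  }
  out
}
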
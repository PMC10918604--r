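#' Specification of a synthetic coastal ocean
#'
#' Describes a rectangular lon/lat domain with a rasterized land mask, a mean
#' alongshore jet, a field of rotational Gaussian eddies, and per-year
#' advection multipliers including rare strong-advection years. The spec is
#' the single source of randomness (via \code{seed}): the same spec and year
#' always produce the same field.
#'
#' @param lonMin,lonMax,latMin,latMax domain bounds in degrees.
#' @param dLon,dLat grid spacing in degrees (> 0).
#' @param days length of the simulated window in days.
#' @param dtDays spacing of stored time slices in days (> 0).
#' @param jetSpeed mean alongshore jet speed, m/s.
#' @param jetDirection jet direction in degrees counterclockwise from east
#'   (90 = northward).
#' @param eddyAmp eddy velocity amplitude, m/s.
#' @param eddyScaleKm eddy e-folding length scale, km.
#' @param nEddies number of Gaussian vortices.
#' @param yearMultipliers named numeric vector of per-year advection
#'   multipliers (dimensionless, >= 0); years absent default to 1.
#' @param rareYears character vector of rare strong-advection year labels.
#' @param rareMultiplier extra multiplier applied in \code{rareYears}.
#' @param jetDirectionByYear optional named numeric vector of per-year jet
#'   direction offsets (degrees), emulating interannual variation in flow
#'   direction.
#' @param landRects list of numeric length-4 vectors
#'   \code{c(lonMin, lonMax, latMin, latMax)} rasterized onto the grid as
#'   land cells.
#' @param seed integer seed for eddy placement.
#' @return a \code{SyntheticOceanSpec} (list).
#' @export
syntheticOceanSpec <- function(lonMin = -11, lonMax = -7, latMin = 40, latMax = 46,
                               dLon = 0.1, dLat = 0.1,
                               days = 22, dtDays = 1,
                               jetSpeed = 0.12, jetDirection = 90,
                               eddyAmp = 0.15, eddyScaleKm = 40, nEddies = 10,
                               yearMultipliers = numeric(),
                               rareYears = character(), rareMultiplier = 3,
                               jetDirectionByYear = numeric(),
                               landRects = list(c(-7.6, -7, 40, 46)),
                               seed = 1L) {
  stopifnot(dLon > 0, dLat > 0, dtDays > 0, days > 0,
            lonMax > lonMin, latMax > latMin,
            jetSpeed >= 0, eddyAmp >= 0, eddyScaleKm > 0,
            all(yearMultipliers >= 0), rareMultiplier >= 0)
  spec <- list(lonMin = lonMin, lonMax = lonMax, latMin = latMin, latMax = latMax,
               dLon = dLon, dLat = dLat, days = days, dtDays = dtDays,
               jetSpeed = jetSpeed, jetDirection = jetDirection,
               eddyAmp = eddyAmp, eddyScaleKm = eddyScaleKm, nEddies = nEddies,
               yearMultipliers = yearMultipliers,
               rareYears = as.character(rareYears), rareMultiplier = rareMultiplier,
               jetDirectionByYear = jetDirectionByYear,
               landRects = landRects, seed = as.integer(seed))
  class(spec) <- "SyntheticOceanSpec"
  spec
}

.rasterizeLand <- function(lon, lat, landRects) {
  land <- matrix(FALSE, length(lon), length(lat))
  for (r in landRects) {
    ii <- lon >= r[1] & lon <= r[2]
    jj <- lat >= r[3] & lat <= r[4]
    land[ii, jj] <- TRUE
  }
  land
}

#' Generate a synthetic velocity field for one year
#'
#' Builds jet + eddy surface currents on the spec's grid. Eddies are a sum of
#' \code{nEddies} randomly placed rotational Gaussian vortices whose centres,
#' signs and strengths depend only on \code{spec$seed}, so interannual
#' differences are controlled entirely by the spec's per-year multipliers and
#' optional jet-direction offsets: a rare-advection year is the base pattern
#' scaled by \code{rareMultiplier}.
#'
#' @param spec a \code{\link{syntheticOceanSpec}}.
#' @param year year label (coerced to character).
#' @return a \linkS4class{VelocityField} with \code{NA} velocities on land.
#' @export
makeVelocityField <- function(spec, year = "2010") {
  stopifnot(inherits(spec, "SyntheticOceanSpec"))
  year <- as.character(year)
  lon <- seq(spec$lonMin, spec$lonMax, by = spec$dLon)
  lat <- seq(spec$latMin, spec$latMax, by = spec$dLat)
  tt <- seq(0, spec$days, by = spec$dtDays)
  land <- .rasterizeLand(lon, lat, spec$landRects)
  if (all(land)) stop("land mask covers the whole domain")

  mult <- 1
  if (year %in% names(spec$yearMultipliers)) mult <- spec$yearMultipliers[[year]]
  if (year %in% spec$rareYears) mult <- mult * spec$rareMultiplier
  dir <- spec$jetDirection
  if (year %in% names(spec$jetDirectionByYear))
    dir <- dir + spec$jetDirectionByYear[[year]]

  nx <- length(lon); ny <- length(lat)
  lonG <- matrix(lon, nx, ny)
  latG <- matrix(lat, nx, ny, byrow = TRUE)
  u2 <- matrix(spec$jetSpeed * cos(dir * pi / 180), nx, ny)
  v2 <- matrix(spec$jetSpeed * sin(dir * pi / 180), nx, ny)

  if (spec$eddyAmp > 0 && spec$nEddies > 0) {
    restoreRng <- .localSeed(.subSeed(spec$seed, "eddies"))
    on.exit(restoreRng(), add = TRUE)
    cx <- runif(spec$nEddies, spec$lonMin, spec$lonMax)
    cy <- runif(spec$nEddies, spec$latMin, spec$latMax)
    sgn <- sample(c(-1, 1), spec$nEddies, replace = TRUE)
    amp <- spec$eddyAmp * runif(spec$nEddies, 0.5, 1)
    L <- spec$eddyScaleKm
    for (k in seq_len(spec$nEddies)) {
      dx <- (lonG - cx[k]) * .KM_PER_DEG * cos(latG * pi / 180)
      dy <- (latG - cy[k]) * .KM_PER_DEG
      g <- exp(-(dx^2 + dy^2) / (2 * L^2))
      u2 <- u2 - sgn[k] * amp[k] * (dy / L) * g
      v2 <- v2 + sgn[k] * amp[k] * (dx / L) * g
    }
  }
  u2 <- u2 * mult
  v2 <- v2 * mult
  # passive-drift substrate: speeds capped at 2 m/s
  u2 <- pmin(pmax(u2, -2), 2)
  v2 <- pmin(pmax(v2, -2), 2)
  u2[land] <- NA_real_
  v2[land] <- NA_real_

  nt <- length(tt)
  u <- array(u2, dim = c(nx, ny, nt))
  v <- array(v2, dim = c(nx, ny, nt))
  new("VelocityField", lon = lon, lat = lat, time = tt, u = u, v = v, land = land)
}

#' Lay out sampling sites on the synthetic ocean
#'
#' Places \code{nSites} pairwise-distinct sites on ocean cells, either along
#' a straight line through the middle of the ocean (\code{"linear"}) or as a
#' north-south transect hugging the land edge at a fixed offshore offset
#' (\code{"coastal"}).
#'
#' @param nSites number of sites (>= 2).
#' @param geometry \code{"linear"} or \code{"coastal"}.
#' @param field a \linkS4class{VelocityField} supplying domain and land mask.
#' @param sampleSizes integer, recycled: planned sample size per site.
#' @param offshoreKm for \code{"coastal"}: distance west of the land edge.
#' @return a site table: \code{data.frame(site, lon, lat, n)}.
#' @export
makeSiteLayout <- function(nSites, geometry = c("coastal", "linear"), field,
                           sampleSizes = 12L, offshoreKm = 15) {
  geometry <- match.arg(geometry)
  if (nSites < 2) stop("nSites must be >= 2")
  lon <- lonAxis(field); lat <- latAxis(field); land <- landMask(field)
  latSeq <- seq(quantile(lat, 0.08), quantile(lat, 0.92), length.out = nSites)
  if (geometry == "linear") {
    ocean <- which(!land, arr.ind = TRUE)
    midJ <- round(stats::median(ocean[, 2]))
    jj <- which(!land[, midJ])
    lonSeq <- seq(lon[quantile(jj, 0.08, type = 1)], lon[quantile(jj, 0.92, type = 1)],
                  length.out = nSites)
    out <- data.frame(site = sprintf("S%02d", seq_len(nSites)),
                      lon = lonSeq, lat = rep(lat[midJ], nSites))
  } else {
    pos <- vapply(latSeq, function(y) {
      j <- which.min(abs(lat - y))
      landI <- which(land[, j])
      edge <- if (length(landI)) lon[min(landI)] else max(lon)
      edge - offshoreKm / (.KM_PER_DEG * cos(y * pi / 180))
    }, numeric(1))
    out <- data.frame(site = sprintf("S%02d", seq_len(nSites)),
                      lon = pos, lat = latSeq)
  }
  out$n <- as.integer(rep_len(sampleSizes, nSites))
  onLand <- vapply(seq_len(nSites),
                   function(i) isLand(field, out$lon[i], out$lat[i]), logical(1))
  if (any(onLand))
    stop("site(s) on land: ", paste(out$site[onLand], collapse = ", "))
  if (anyDuplicated(out[, c("lon", "lat")]))
    stop("sites must be pairwise distinct")
  out
}
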
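#' Write a velocity field to NetCDF
#'
#' CF-style layout: dimensions \code{longitude}, \code{latitude}, \code{time}
#' (days); variables \code{uo}, \code{vo} in m/s with land cells as fill
#' values. Files written here round-trip through
#' \code{\link{readVelocityField}} and the same reader handles CMEMS-like
#' products with the same variable names.
#'
#' @param field a \linkS4class{VelocityField}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeVelocityField <- function(field, path) {
  fill <- 9.96921e36
  dimLon <- ncdf4::ncdim_def("longitude", "degrees_east", lonAxis(field))
  dimLat <- ncdf4::ncdim_def("latitude", "degrees_north", latAxis(field))
  dimT <- ncdf4::ncdim_def("time", "days since 2000-01-01 00:00:00",
                           timeAxis(field), unlim = TRUE)
  vu <- ncdf4::ncvar_def("uo", "m s-1", list(dimLon, dimLat, dimT), fill,
                         prec = "double")
  vv <- ncdf4::ncvar_def("vo", "m s-1", list(dimLon, dimLat, dimT), fill,
                         prec = "double")
  nc <- ncdf4::nc_create(path, list(vu, vv))
  on.exit(ncdf4::nc_close(nc))
  u <- field@u; v <- field@v
  u[is.na(u)] <- fill; v[is.na(v)] <- fill
  ncdf4::ncvar_put(nc, vu, u)
  ncdf4::ncvar_put(nc, vv, v)
  invisible(path)
}

#' Read a gridded velocity field from NetCDF
#'
#' Axes are returned ascending (arrays flipped when stored descending);
#' cells where either velocity component is missing are marked land.
#'
#' @param path NetCDF file.
#' @param varNames named list mapping roles to variable/dimension names;
#'   defaults \code{uo/vo/longitude/latitude/time}.
#' @return a \linkS4class{VelocityField}.
#' @export
readVelocityField <- function(path,
                              varNames = list(u = "uo", v = "vo",
                                              lon = "longitude",
                                              lat = "latitude",
                                              time = "time")) {
  if (!file.exists(path)) stop("file not found: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  have <- c(names(nc$var), names(nc$dim))
  for (role in c("u", "v", "lon", "lat", "time")) {
    if (!varNames[[role]] %in% have)
      stop("variable '", varNames[[role]], "' (", role, ") not found in ", path)
  }
  lon <- as.numeric(ncdf4::ncvar_get(nc, varNames$lon))
  lat <- as.numeric(ncdf4::ncvar_get(nc, varNames$lat))
  tt <- as.numeric(ncdf4::ncvar_get(nc, varNames$time))
  u <- ncdf4::ncvar_get(nc, varNames$u, collapse_degen = FALSE)
  v <- ncdf4::ncvar_get(nc, varNames$v, collapse_degen = FALSE)
  if (length(dim(u)) == 2L) { dim(u) <- c(dim(u), 1L); dim(v) <- c(dim(v), 1L) }
  if (length(tt) > 2) {
    dt <- diff(tt)
    if (max(dt) - min(dt) > 1e-6 * max(abs(dt)))
      stop("irregular time axis in variable '", varNames$time, "'")
  }
  if (is.unsorted(lon)) { o <- order(lon); lon <- lon[o]; u <- u[o, , , drop = FALSE]; v <- v[o, , , drop = FALSE] }
  if (is.unsorted(lat)) { o <- order(lat); lat <- lat[o]; u <- u[, o, , drop = FALSE]; v <- v[, o, , drop = FALSE] }
  if (is.unsorted(tt)) { o <- order(tt); tt <- tt[o]; u <- u[, , o, drop = FALSE]; v <- v[, , o, drop = FALSE] }
  land <- is.na(u[, , 1]) | is.na(v[, , 1])
  for (k in seq_along(tt)) {
    miss <- is.na(u[, , k]) | is.na(v[, , k])
    land <- land | miss
  }
  u[rep(land, length(tt))] <- NA_real_
  v[rep(land, length(tt))] <- NA_real_
  new("VelocityField", lon = lon, lat = lat, time = tt, u = u, v = v, land = land)
}

#' Interpolate velocity at arbitrary points and times
#'
#' Bilinear in space, linear in time. Land cells among the four spatial
#' neighbours contribute zero velocity and the bilinear weights are
#' renormalized over the ocean cells; a query whose four neighbours are all
#' land returns \code{NA} for both components (the "on land" signal).
#' Queries outside the grid bounds or time span are an error, distinct from
#' the on-land signal.
#'
#' @param field a \linkS4class{VelocityField}.
#' @param lon,lat query coordinates (vectors of equal length, degrees).
#' @param t query time in days (scalar).
#' @return list with numeric vectors \code{u} and \code{v} (m/s); \code{NA}
#'   where the query point is surrounded by land.
#' @export
sampleVelocity <- function(field, lon, lat, t) {
  gx <- field@lon; gy <- field@lat; gt <- field@time
  if (any(lon < gx[1] | lon > gx[length(gx)] |
          lat < gy[1] | lat > gy[length(gy)]))
    stop("query point outside grid domain")
  if (t < gt[1] - 1e-9 || t > gt[length(gt)] + 1e-9)
    stop("query time outside field time span")
  t <- min(max(t, gt[1]), gt[length(gt)])

  kt <- findInterval(t, gt, rightmost.closed = TRUE)
  kt <- min(max(kt, 1L), length(gt) - 1L)
  if (length(gt) == 1L) { kt <- 1L; wt <- 0 } else {
    wt <- (t - gt[kt]) / (gt[kt + 1L] - gt[kt])
  }

  ix <- findInterval(lon, gx, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(gx) - 1L)
  iy <- findInterval(lat, gy, rightmost.closed = TRUE)
  iy <- pmin(pmax(iy, 1L), length(gy) - 1L)
  wx <- (lon - gx[ix]) / (gx[ix + 1L] - gx[ix])
  wy <- (lat - gy[iy]) / (gy[iy + 1L] - gy[iy])

  w <- cbind((1 - wx) * (1 - wy), wx * (1 - wy), (1 - wx) * wy, wx * wy)
  nx <- length(gx)
  cellIdx <- cbind(ix + (iy - 1L) * nx,          # (i, j)
                   ix + 1L + (iy - 1L) * nx,     # (i+1, j)
                   ix + iy * nx,                 # (i, j+1)
                   ix + 1L + iy * nx)            # (i+1, j+1)

  interp1 <- function(slice) {
    vals <- matrix(slice[cellIdx], nrow = length(lon))
    wEff <- w
    wEff[is.na(vals)] <- 0
    vals[is.na(vals)] <- 0
    tot <- rowSums(wEff)
    out <- rowSums(wEff * vals) / tot
    out[tot <= 0] <- NA_real_
    out
  }
  uk <- interp1(field@u[, , kt]); vk <- interp1(field@v[, , kt])
  if (length(gt) == 1L || wt == 0) return(list(u = uk, v = vk))
  uk1 <- interp1(field@u[, , kt + 1L]); vk1 <- interp1(field@v[, , kt + 1L])
  list(u = (1 - wt) * uk + wt * uk1, v = (1 - wt) * vk + wt * vk1)
}

#' Is a point on land?
#'
#' Nearest-cell semantics: a point is land iff the grid cell whose centre is
#' nearest to it is masked. Midpoints between cell centres round to the
#' higher index (the cell to the east/north).
#'
#' @param field a \linkS4class{VelocityField}.
#' @param lon,lat coordinates (vectors of equal length).
#' @return logical vector.
#' @export
isLand <- function(field, lon, lat) {
  gx <- field@lon; gy <- field@lat
  if (any(lon < gx[1] | lon > gx[length(gx)] |
          lat < gy[1] | lat > gy[length(gy)]))
    stop("point outside grid domain")
  i <- findInterval(lon, gx, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(gx) - 1L)
  i <- i + as.integer(lon - gx[i] >= gx[i + 1L] - lon)
  j <- findInterval(lat, gy, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), length(gy) - 1L)
  j <- j + as.integer(lat - gy[j] >= gy[j + 1L] - lat)
  field@land[cbind(i, j)]
}
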
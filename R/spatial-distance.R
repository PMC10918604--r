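#' Marine least-cost distances between sites
#'
#' Shortest ocean-only path on the velocity grid treated as an 8-connected
#' graph (Dijkstra via igraph). Horizontal/vertical step lengths use the
#' latitude-corrected local-tangent metric and diagonal steps their Euclidean
#' combination. When the straight segment between two sites crosses no land
#' cell the great-circle distance is returned directly, so the no-obstacle
#' limit is exact. Pairs with no ocean path get \code{Inf} and a warning.
#'
#' @param field a \linkS4class{VelocityField} supplying grid and land mask.
#' @param sites site table (\code{site, lon, lat}); all sites must be on
#'   ocean cells.
#' @return symmetric matrix of distances in km, zero diagonal, site names as
#'   dimnames.
#' @export
leastCostDistance <- function(field, sites) {
  lon <- lonAxis(field); lat <- latAxis(field); land <- landMask(field)
  onLand <- isLand(field, sites$lon, sites$lat)
  if (any(onLand))
    stop("site(s) on land: ", paste(sites$site[onLand], collapse = ", "))
  nx <- length(lon); ny <- length(lat)
  dLon <- mean(diff(lon)); dLat <- mean(diff(lat))

  nodeId <- matrix(0L, nx, ny)
  ocean <- which(!land)
  nodeId[ocean] <- seq_along(ocean)

  edges <- list(); w <- list(); e <- 0L
  addEdges <- function(di, dj, lenFun) {
    i0 <- seq_len(nx - max(di, 0)); if (di < 0) i0 <- seq(1 - di, nx)
    j0 <- seq_len(ny - max(dj, 0)); if (dj < 0) j0 <- seq(1 - dj, ny)
    A <- nodeId[i0, j0, drop = FALSE]
    B <- nodeId[i0 + di, j0 + dj, drop = FALSE]
    ok <- A > 0L & B > 0L
    if (!any(ok)) return(invisible())
    latPair <- (matrix(lat[j0], length(i0), length(j0), byrow = TRUE) +
                matrix(lat[j0 + dj], length(i0), length(j0), byrow = TRUE)) / 2
    e <<- e + 1L
    edges[[e]] <<- rbind(A[ok], B[ok])
    w[[e]] <<- lenFun(latPair[ok])
  }
  dxKm <- function(latMid) .KM_PER_DEG * cos(latMid * pi / 180) * dLon
  dyKm <- .KM_PER_DEG * dLat
  addEdges(1L, 0L, function(lm) dxKm(lm))
  addEdges(0L, 1L, function(lm) rep(dyKm, length(lm)))
  addEdges(1L, 1L, function(lm) sqrt(dxKm(lm)^2 + dyKm^2))
  addEdges(1L, -1L, function(lm) sqrt(dxKm(lm)^2 + dyKm^2))
  gr <- igraph::make_graph(as.vector(do.call(cbind, edges)),
                           n = length(ocean), directed = FALSE)

  cellOf <- function(x, y) {
    i <- which.min(abs(lon - x)); j <- which.min(abs(lat - y))
    nodeId[i, j]
  }
  siteNode <- mapply(cellOf, sites$lon, sites$lat)
  D <- igraph::distances(gr, v = siteNode, to = siteNode,
                         weights = unlist(w), algorithm = "dijkstra")
  dimnames(D) <- list(sites$site, sites$site)

  # straight-line replacement where no land intervenes
  seesLand <- function(i, j) {
    steps <- max(2L, ceiling(3 * max(abs(sites$lon[i] - sites$lon[j]) / dLon,
                                     abs(sites$lat[i] - sites$lat[j]) / dLat)))
    f <- seq(0, 1, length.out = steps)
    any(isLand(field, sites$lon[i] + f * (sites$lon[j] - sites$lon[i]),
               sites$lat[i] + f * (sites$lat[j] - sites$lat[i])))
  }
  ns <- nrow(sites)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    if (!seesLand(i, j)) {
      D[i, j] <- D[j, i] <- haversineKm(sites$lon[i], sites$lat[i],
                                        sites$lon[j], sites$lat[j])
    }
  }
  diag(D) <- 0
  if (any(!is.finite(D)))
    warning("some site pairs have no ocean path (Inf distance)")
  D
}
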
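# Local-tangent metric: 1 deg lat = 111.32 km, 1 deg lon = 111.32 cos(lat) km.
# Matches the great-circle radius used by geosphere (6378137 m) to < 0.01%.
.KM_PER_DEG <- 111.32

#' Great-circle distance in kilometres
#'
#' Haversine distance between points given as (lon, lat) degrees.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees; vectors are recycled.
#' @return numeric distances in km.
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# metres/second -> degrees/day at a given latitude
.uToDegPerDay <- function(u, lat) {
  u * 86.4 / (.KM_PER_DEG * cos(lat * pi / 180))
}
.vToDegPerDay <- function(v) {
  v * 86.4 / .KM_PER_DEG
}

# deterministic sub-seed derivation (keeps results < 2^31)
.subSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  ints <- utf8ToInt(key)
  h <- 0
  for (v in ints) h <- (h * 131 + v) %% 2147483587
  as.integer(h) + 1L
}

# seed the RNG locally: returns a restore function for use with on.exit(),
# so package functions never disturb the caller's random stream
.localSeed <- function(seed) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    env$.Random.seed else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  }
}
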
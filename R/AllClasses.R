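#' @import methods
NULL

#' Gridded surface-current velocity field
#'
#' Holds u/v surface velocities (m/s) on a regular lon/lat grid over a
#' regular time axis, plus a cell-level land mask. Velocities are \code{NA}
#' on land cells. The time axis is in days since an arbitrary origin (the
#' release clock); grids are always stored with both axes ascending.
#'
#' @slot lon numeric, ascending longitude axis (degrees east).
#' @slot lat numeric, ascending latitude axis (degrees north).
#' @slot time numeric, ascending regular time axis (days).
#' @slot u,v numeric arrays \code{[lon, lat, time]} in m/s, \code{NA} on land.
#' @slot land logical matrix \code{[lon, lat]}; \code{TRUE} = land cell.
#'
#' @export
setClass("VelocityField",
  representation(
    lon = "numeric", lat = "numeric", time = "numeric",
    u = "array", v = "array", land = "matrix"
  )
)

setValidity("VelocityField", function(object) {
  msg <- character()
  if (length(object@lon) < 2 || any(diff(object@lon) <= 0))
    msg <- c(msg, "lon axis must be strictly ascending with length >= 2")
  if (length(object@lat) < 2 || any(diff(object@lat) <= 0))
    msg <- c(msg, "lat axis must be strictly ascending with length >= 2")
  if (length(object@time) < 1 || any(diff(object@time) <= 0))
    msg <- c(msg, "time axis must be strictly ascending")
  if (length(object@time) > 2) {
    dt <- diff(object@time)
    if (max(dt) - min(dt) > 1e-6 * max(dt))
      msg <- c(msg, "time axis must be regular")
  }
  dms <- c(length(object@lon), length(object@lat), length(object@time))
  if (!identical(dim(object@u), dms)) msg <- c(msg, "dim(u) must be [lon, lat, time]")
  if (!identical(dim(object@v), dms)) msg <- c(msg, "dim(v) must be [lon, lat, time]")
  if (!identical(dim(object@land), dms[1:2])) msg <- c(msg, "land mask shape must match grid")
  if (all(object@land)) msg <- c(msg, "land mask covers the whole domain")
  ocean <- !object@land
  if (length(msg) == 0L) {
    for (k in seq_along(object@time)) {
      if (any(!is.finite(object@u[, , k][ocean])) || any(!is.finite(object@v[, , k][ocean]))) {
        msg <- c(msg, "u and v must be finite on ocean cells")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-particle trajectories for one site-year release
#'
#' Positions are stored at daily snapshots (plus the release instant);
#' particles that collide with land or leave the domain are marked dead and
#' carry \code{NA} positions from their death snapshot onwards.
#'
#' @slot lon,lat numeric matrices \code{[particle, snapshot]} (degrees).
#' @slot times numeric snapshot times in days since release.
#' @slot deathTime numeric per particle: days since release at death,
#'   \code{NA} for survivors.
#' @slot release list with at least \code{site}, \code{lon}, \code{lat},
#'   \code{year}, \code{nParticles}, \code{start} (days on the field clock),
#'   \code{duration} (days).
#'
#' @export
setClass("TrajectorySet",
  representation(
    lon = "matrix", lat = "matrix", times = "numeric",
    deathTime = "numeric", release = "list"
  )
)

setValidity("TrajectorySet", function(object) {
  msg <- character()
  if (!identical(dim(object@lon), dim(object@lat)))
    msg <- c(msg, "lon/lat matrices must have identical shape")
  if (ncol(object@lon) != length(object@times))
    msg <- c(msg, "number of snapshots must match times")
  if (nrow(object@lon) != length(object@deathTime))
    msg <- c(msg, "deathTime must have one entry per particle")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "snapshot times must be ascending")
  # dead particles must not have positions after death
  if (length(msg) == 0L && any(!is.na(object@deathTime))) {
    dead <- which(!is.na(object@deathTime))
    for (i in dead) {
      after <- object@times > object@deathTime[i] + 1e-9
      if (any(!is.na(object@lon[i, after])))
        { msg <- c(msg, "dead particles carry positions after death"); break }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Site-to-site dispersal probability matrices
#'
#' \code{P[i, j]} is the proportion of particles released from site i that
#' are credited to site j's source zone (a great-circle disc of
#' \code{radiusKm} about the site) for a given pelagic larval duration.
#' The diagonal is self-recruitment. Rows need not sum to one: zones can
#' overlap or be missed entirely.
#'
#' @slot sites character, ordered site names.
#' @slot yearly named list of site-by-site matrices, one per year.
#' @slot mean site-by-site matrix, elementwise mean across years
#'   (\code{NA} rows ignored).
#' @slot pld numeric, pelagic larval duration in days.
#' @slot radiusKm numeric, buffer-zone radius.
#' @slot convention character, \code{"snapshot"} (membership at the PLD-day
#'   snapshot) or \code{"any_time"} (entered the zone at any snapshot).
#'
#' @export
setClass("ConnectivityMatrix",
  representation(
    sites = "character", yearly = "list", mean = "matrix",
    pld = "numeric", radiusKm = "numeric", convention = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  ns <- length(object@sites)
  if (!identical(dim(object@mean), c(ns, ns)))
    msg <- c(msg, "mean matrix must be sites x sites")
  for (M in object@yearly) {
    if (!identical(dim(M), c(ns, ns))) { msg <- c(msg, "yearly matrix shape mismatch"); break }
    ok <- M[is.finite(M)]
    if (length(ok) && (min(ok) < -1e-12 || max(ok) > 1 + 1e-12))
      { msg <- c(msg, "probabilities must lie in [0, 1]"); break }
  }
  if (!object@convention %in% c("snapshot", "any_time"))
    msg <- c(msg, "convention must be 'snapshot' or 'any_time'")
  if (length(msg)) msg else TRUE
})

#' Diploid biallelic genotype matrix
#'
#' Individuals by loci, coded as copies of the alternate allele (0/1/2),
#' \code{NA} for missing calls. Every individual carries a site label.
#'
#' @slot geno integer matrix \code{[individual, locus]} with values in
#'   \{0, 1, 2, NA\}; dimnames give individual and locus ids.
#' @slot site character site label per individual.
#' @slot chrom character chromosome/contig per locus.
#' @slot pos integer position per locus.
#'
#' @export
setClass("GenotypeMatrix",
  representation(geno = "matrix", site = "character",
                 chrom = "character", pos = "integer")
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  g <- object@geno
  if (!is.numeric(g)) msg <- c(msg, "geno must be numeric/integer")
  else {
    vals <- g[!is.na(g)]
    if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
      msg <- c(msg, "genotype calls must be 0, 1, 2 or NA")
  }
  if (nrow(g) != length(object@site))
    msg <- c(msg, "one site label per individual required")
  if (length(object@chrom) && length(object@chrom) != ncol(g))
    msg <- c(msg, "chrom must have one entry per locus")
  if (length(object@pos) && length(object@pos) != ncol(g))
    msg <- c(msg, "pos must have one entry per locus")
  if (length(msg)) msg else TRUE
})

#' Ordered spatial eigenvector basis (dbMEM or AEM)
#'
#' @slot kind character, \code{"dbMEM"} or \code{"AEM"}.
#' @slot scores matrix \code{[site, vector]}, centred, mutually orthogonal.
#' @slot values numeric eigenvalues (dbMEM) or squared singular values (AEM),
#'   descending, one per retained vector.
#' @slot meta list of construction metadata (truncation threshold, edges, ...).
#'
#' @export
setClass("EigenbasisSet",
  representation(kind = "character", scores = "matrix",
                 values = "numeric", meta = "list")
)

setValidity("EigenbasisSet", function(object) {
  msg <- character()
  if (!object@kind %in% c("dbMEM", "AEM")) msg <- c(msg, "kind must be dbMEM or AEM")
  if (ncol(object@scores) != length(object@values))
    msg <- c(msg, "one value per score vector required")
  if (ncol(object@scores) > nrow(object@scores) - 1L)
    msg <- c(msg, "at most n_sites - 1 vectors allowed")
  if (length(object@values) > 1 && any(diff(object@values) > 1e-8))
    msg <- c(msg, "values must be in descending order")
  if (length(msg)) msg else TRUE
})

#' Redundancy analysis result
#'
#' @slot r2 numeric, constrained R^2 (SS fitted / SS total).
#' @slot adjR2 numeric, Ezekiel-adjusted R^2.
#' @slot eig numeric, canonical axis eigenvalues.
#' @slot axisP numeric, per-axis permutation p-values.
#' @slot globalP numeric, global permutation p-value.
#' @slot vif named numeric, variance inflation factor per predictor.
#' @slot fractions list of variance fractions for partial analyses.
#' @slot details list (fitted values, coefficients, permutation count, ...).
#'
#' @export
setClass("RdaResult",
  representation(r2 = "numeric", adjR2 = "numeric", eig = "numeric",
                 axisP = "numeric", globalP = "numeric", vif = "numeric",
                 fractions = "list", details = "list")
)
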
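#' @rdname VelocityField-class
#' @export
setMethod("lonAxis", "VelocityField", function(object) object@lon)

#' @rdname VelocityField-class
#' @export
setMethod("latAxis", "VelocityField", function(object) object@lat)

#' @rdname VelocityField-class
#' @export
setMethod("timeAxis", "VelocityField", function(object) object@time)

#' @rdname VelocityField-class
#' @export
setMethod("landMask", "VelocityField", function(object) object@land)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(object) object@geno)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("siteLabels", "GenotypeMatrix", function(object) object@site)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("lociInfo", "GenotypeMatrix", function(object) {
  data.frame(locus = colnames(object@geno),
             chrom = if (length(object@chrom)) object@chrom else NA_character_,
             pos = if (length(object@pos)) object@pos else NA_integer_,
             stringsAsFactors = FALSE)
})

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("connMean", "ConnectivityMatrix", function(object) object@mean)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("connYearly", "ConnectivityMatrix", function(object) object@yearly)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("siteNames", "ConnectivityMatrix", function(object) object@sites)

#' @rdname EigenbasisSet-class
#' @export
setMethod("basisScores", "EigenbasisSet", function(object) object@scores)

#' @rdname EigenbasisSet-class
#' @export
setMethod("basisValues", "EigenbasisSet", function(object) object@values)

#' @rdname TrajectorySet-class
#' @export
setMethod("deathTimes", "TrajectorySet", function(object) object@deathTime)

#' @rdname TrajectorySet-class
#' @export
setMethod("snapshotPositions", "TrajectorySet", function(object, day) {
  k <- which(abs(object@times - day) < 1e-9)
  if (length(k) != 1L)
    stop("no snapshot stored at day ", day)
  data.frame(lon = object@lon[, k], lat = object@lat[, k],
             alive = is.na(object@deathTime) | object@deathTime > day + 1e-9)
})

setMethod("show", "VelocityField", function(object) {
  cat("VelocityField:", length(object@lon), "x", length(object@lat), "grid,",
      length(object@time), "time steps\n")
  cat("  lon [", min(object@lon), ",", max(object@lon), "] lat [",
      min(object@lat), ",", max(object@lat), "]\n")
  cat("  time [", min(object@time), ",", max(object@time), "] days;",
      sum(object@land), "land cells (",
      round(100 * mean(object@land), 1), "% )\n")
})

setMethod("show", "TrajectorySet", function(object) {
  n <- nrow(object@lon)
  cat("TrajectorySet: site", object@release$site, "year",
      object@release$year, "-", n, "particles,",
      length(object@times), "snapshots\n")
  cat("  dead:", sum(!is.na(object@deathTime)), "/", n, "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix:", length(object@sites), "sites,",
      length(object@yearly), "years, PLD", object@pld, "d, buffer",
      object@radiusKm, "km (", object@convention, ")\n")
  cat("  mean self-recruitment:",
      round(mean(diag(object@mean), na.rm = TRUE), 4), "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@geno), "individuals x",
      ncol(object@geno), "loci,", length(unique(object@site)), "sites\n")
  cat("  missing calls:",
      round(100 * mean(is.na(object@geno)), 2), "%\n")
})

setMethod("show", "EigenbasisSet", function(object) {
  cat(object@kind, "basis:", ncol(object@scores), "vectors over",
      nrow(object@scores), "sites\n")
})

setMethod("show", "RdaResult", function(object) {
  cat("RDA: R2 =", round(object@r2, 4), " adjR2 =", round(object@adjR2, 4),
      " global p =", object@globalP, "\n")
})
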
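#' @rdname VelocityField-class
#' @param object,field a \linkS4class{VelocityField}
#' @export
setGeneric("lonAxis", function(object) standardGeneric("lonAxis"))

#' @rdname VelocityField-class
#' @export
setGeneric("latAxis", function(object) standardGeneric("latAxis"))

#' @rdname VelocityField-class
#' @export
setGeneric("timeAxis", function(object) standardGeneric("timeAxis"))

#' @rdname VelocityField-class
#' @export
setGeneric("landMask", function(object) standardGeneric("landMask"))

#' @rdname GenotypeMatrix-class
#' @param object a \linkS4class{GenotypeMatrix}
#' @export
setGeneric("genotypeCalls", function(object) standardGeneric("genotypeCalls"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("siteLabels", function(object) standardGeneric("siteLabels"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("lociInfo", function(object) standardGeneric("lociInfo"))

#' @rdname ConnectivityMatrix-class
#' @param object a \linkS4class{ConnectivityMatrix}
#' @export
setGeneric("connMean", function(object) standardGeneric("connMean"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("connYearly", function(object) standardGeneric("connYearly"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("siteNames", function(object) standardGeneric("siteNames"))

#' @rdname EigenbasisSet-class
#' @param object an \linkS4class{EigenbasisSet}
#' @export
setGeneric("basisScores", function(object) standardGeneric("basisScores"))

#' @rdname EigenbasisSet-class
#' @export
setGeneric("basisValues", function(object) standardGeneric("basisValues"))

#' @rdname TrajectorySet-class
#' @param object a \linkS4class{TrajectorySet}
#' @export
setGeneric("deathTimes", function(object) standardGeneric("deathTimes"))

#' @rdname TrajectorySet-class
#' @param day snapshot day (days since release)
#' @export
setGeneric("snapshotPositions",
           function(object, day) standardGeneric("snapshotPositions"))
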
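#' Accessor generics
#'
#' Small accessor layer over the package's S4 containers; user code should
#' prefer these to direct slot access.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors region-by-receptor density matrix of a
#'   [ReceptorAtlas-class] (regions in rows).
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))

#' @describeIn accessors parcel labels.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @describeIn accessors pairwise Euclidean centroid distance matrix, mm.
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @describeIn accessors unit sphere-projection coordinates.
#' @export
setGeneric("sphereCoords", function(x) standardGeneric("sphereCoords"))

#' @describeIn accessors centroid coordinates, mm.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @describeIn accessors hemisphere label per region.
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))

#' @describeIn accessors spin assignment index matrix of a
#'   [SpinEnsemble-class].
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @describeIn accessors null matrices of a [RewiredEnsemble-class].
#' @export
setGeneric("nullMatrices", function(x) standardGeneric("nullMatrices"))

#' @describeIn accessors receptor/transporter metadata of a
#'   [ReceptorAtlas-class] (study n, mean age, class annotations).
#' @export
setGeneric("receptorMeta", function(x) standardGeneric("receptorMeta"))

#' @describeIn accessors singular values of a [PLSResult-class].
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @describeIn accessors covariance-explained fractions of a
#'   [PLSResult-class].
#' @export
setGeneric("covExplained", function(x) standardGeneric("covExplained"))

#' @describeIn accessors total dominance per predictor of a
#'   [DominanceResult-class].
#' @export
setGeneric("totalDominance", function(x) standardGeneric("totalDominance"))

#' @describeIn accessors percent dominance shares of a
#'   [DominanceResult-class].
#' @export
setGeneric("percentDominance", function(x) standardGeneric("percentDominance"))
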
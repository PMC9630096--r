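#' @importFrom SummarizedExperiment assay assayNames rowData colData
NULL

#' @rdname accessors
#' @export
setMethod("densities", "ReceptorAtlas", function(x) {
  t(SummarizedExperiment::assay(x, "density"))
})

#' @rdname accessors
#' @export
setMethod("regionIds", "ParcelGeometry", function(x) x@regionIds)

#' @rdname accessors
#' @export
setMethod("regionIds", "ReceptorAtlas", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("distanceMatrix", "ParcelGeometry", function(x) x@distance)

#' @rdname accessors
#' @export
setMethod("sphereCoords", "ParcelGeometry", function(x) x@sphereCoords)

#' @rdname accessors
#' @export
setMethod("centroids", "ParcelGeometry", function(x) x@centroids)

#' @rdname accessors
#' @export
setMethod("hemispheres", "ParcelGeometry", function(x) x@hemisphere)

#' @rdname accessors
#' @export
setMethod("assignments", "SpinEnsemble", function(x) x@assignments)

#' @rdname accessors
#' @export
setMethod("nullMatrices", "RewiredEnsemble", function(x) x@matrices)

#' @rdname accessors
#' @export
setMethod("receptorMeta", "ReceptorAtlas", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname accessors
#' @export
setMethod("singularValues", "PLSResult", function(x) x@singularValues)

#' @rdname accessors
#' @export
setMethod("covExplained", "PLSResult", function(x) x@covExplained)

#' @rdname accessors
#' @export
setMethod("totalDominance", "DominanceResult", function(x) x@total)

#' @rdname accessors
#' @export
setMethod("percentDominance", "DominanceResult", function(x) x@percent)

#' @importFrom stats coefficients
#' @export
setMethod("coefficients", "MultilinearResult", function(object, ...) {
  object@coefficients
})

setMethod("show", "ParcelGeometry", function(object) {
  n <- length(object@regionIds)
  tab <- table(object@hemisphere)
  cat("ParcelGeometry with", n, "regions (",
      tab[["left"]], "left /", tab[["right"]], "right )\n")
  cat("  centroid distance range:",
      sprintf("%.1f-%.1f mm", min(object@distance[upper.tri(object@distance)]),
              max(object@distance)), "\n")
  cat("  medial wall marker:",
      if (nrow(object@medialWall)) "present" else "absent", "\n")
})

setMethod("show", "ReceptorAtlas", function(object) {
  cat("ReceptorAtlas:", ncol(object), "regions x", nrow(object),
      "receptors/transporters (z-scored densities)\n")
  callNextMethod()
})

setMethod("show", "SpinEnsemble", function(object) {
  cat("SpinEnsemble:", nrow(object@assignments), "rotations over",
      ncol(object@assignments), "regions (seed", object@seed, ")\n")
})

setMethod("show", "RewiredEnsemble", function(object) {
  cat("RewiredEnsemble:", length(object@matrices),
      "length-binned degree-preserving nulls,",
      length(object@binEdges) - 1, "distance bins\n")
  cat("  accepted swaps per null: median",
      stats::median(object@nSwaps), "\n")
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf(
    "DecayFit: similarity = %.4f * exp(-%.4f * d) + %.4f  (rss %.4g, %d pairs)\n",
    object@amplitude, object@rate, object@offset, object@rss, object@nPairs))
})

setMethod("show", "MultilinearResult", function(object) {
  cat(sprintf("MultilinearResult: R2 = %.3f, adjusted R2 = %.3f (n = %d)\n",
              object@r2, object@r2adj, object@n))
  if (is.finite(object@pSpin)) cat(sprintf("  p_spin = %.4g\n", object@pSpin))
})

setMethod("show", "DominanceResult", function(object) {
  cat(sprintf("DominanceResult over %d predictors (full-model R2 = %.3f)\n",
              length(object@total), object@r2full))
  top <- sort(object@percent, decreasing = TRUE)
  top <- utils::head(top, 3)
  cat("  leading shares (% of R2):",
      paste(sprintf("%s %.1f", names(top), top), collapse = ", "), "\n")
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: %d distance-dependent folds, mean test r = %.3f\n",
    length(object@testR), object@meanTestR))
  if (is.finite(object@pNull)) cat(sprintf("  p_null = %.4g\n", object@pNull))
})

setMethod("show", "PLSResult", function(object) {
  cat("PLSResult with", length(object@singularValues), "latent variables\n")
  cat(sprintf("  LV1 covariance explained: %.1f%%\n",
              100 * object@covExplained[1]))
  if (any(is.finite(object@pSpin))) {
    cat(sprintf("  LV1 p_spin = %.4g\n", object@pSpin[1]))
  }
})

setMethod("show", "CouplingResult", function(object) {
  cat("CouplingResult over", length(object@regionIds), "regions\n")
  cat(sprintf("  mean delta adjusted R2 = %.4f; %d regions significant (FDR)\n",
              mean(object@delta), sum(object@significant, na.rm = TRUE)))
})
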
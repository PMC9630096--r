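#' @import methods
#' @importFrom stats sd cor
NULL

#' ParcelGeometry: geometry of a cortical parcellation
#'
#' Holds, for every cortical parcel, its Euclidean centroid (mm), its unit
#' vector on the spherical surface projection of its hemisphere, and its
#' hemisphere label, together with the full pairwise Euclidean distance
#' matrix between centroids. The spherical coordinates drive the spin
#' permutation null model; the centroid distances drive distance-decay fits,
#' edge-length binning and distance-dependent cross-validation.
#'
#' @slot regionIds character vector of parcel labels.
#' @slot centroids numeric matrix (regions x 3) of centroid coordinates, mm.
#' @slot sphereCoords numeric matrix (regions x 3) of unit vectors on the
#'   spherical projection of each hemisphere.
#' @slot hemisphere character vector, `"left"` or `"right"` per region.
#' @slot medialWall numeric matrix (2 x 3, rows `left`/`right`) of unit
#'   vectors marking the medial-wall location on each hemisphere sphere, or a
#'   0-row matrix when no marker is defined.
#' @slot distance symmetric numeric matrix of pairwise centroid distances, mm.
#'
#' @seealso [generateParcellation()], [buildSpinEnsemble()]
#' @export
setClass("ParcelGeometry",
  representation(
    regionIds = "character",
    centroids = "matrix",
    sphereCoords = "matrix",
    hemisphere = "character",
    medialWall = "matrix",
    distance = "matrix"
  )
)

setValidity("ParcelGeometry", function(object) {
  n <- length(object@regionIds)
  msg <- character(0)
  if (nrow(object@centroids) != n || ncol(object@centroids) != 3) {
    msg <- c(msg, "centroids must be an n x 3 matrix")
  }
  if (nrow(object@sphereCoords) != n || ncol(object@sphereCoords) != 3) {
    msg <- c(msg, "sphereCoords must be an n x 3 matrix")
  }
  if (length(object@hemisphere) != n ||
      !all(object@hemisphere %in% c("left", "right"))) {
    msg <- c(msg, "hemisphere must be 'left'/'right' per region")
  } else if (any(table(factor(object@hemisphere,
                              c("left", "right"))) < 2)) {
    msg <- c(msg, "each hemisphere needs at least 2 regions")
  }
  if (nrow(object@distance) != n || ncol(object@distance) != n) {
    msg <- c(msg, "distance must be n x n")
  } else {
    if (max(abs(object@distance - t(object@distance))) > 1e-8) {
      msg <- c(msg, "distance must be symmetric")
    }
    if (any(abs(diag(object@distance)) > 1e-10)) {
      msg <- c(msg, "distance diagonal must be zero")
    }
    d2 <- as.matrix(stats::dist(object@centroids))
    if (max(abs(d2 - object@distance)) > 1e-6) {
      msg <- c(msg, "distance must equal Euclidean centroid distances")
    }
  }
  norms <- sqrt(rowSums(object@sphereCoords^2))
  if (length(norms) == n && any(abs(norms - 1) > 1e-9)) {
    msg <- c(msg, "sphereCoords rows must have unit norm (tol 1e-9)")
  }
  if (nrow(object@medialWall) > 0 &&
      (nrow(object@medialWall) != 2 || ncol(object@medialWall) != 3)) {
    msg <- c(msg, "medialWall must be a 2 x 3 matrix (left, right) or empty")
  }
  if (length(msg)) msg else TRUE
})

#' ReceptorAtlas: parcellated receptor/transporter density atlas
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the region-by-
#' receptor matrix of relative densities. Receptors/transporters are rows
#' (features, with study metadata and class annotations in `rowData`);
#' parcels are columns (samples). Each receptor map is z-scored across
#' regions (sample sd), so values are unitless relative densities. Use
#' [densities()] for the conventional regions x receptors orientation used
#' by the statistical machinery.
#'
#' Expected `rowData` columns: `studyN` (pooled participant count), `meanAge`
#' (mean participant age, years) and any of the class annotations
#' `excitatory` (logical), `ionotropic` (logical), `monoamine` (logical),
#' `gProtein` (`"Gs"`/`"Gi"`/`"Gq"`/`NA`).
#'
#' @seealso [assembleAtlas()], [generateReceptorAtlas()], [densities()]
#' @export
setClass("ReceptorAtlas", contains = "SummarizedExperiment")

setValidity("ReceptorAtlas", function(object) {
  msg <- character(0)
  if (!"density" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'density' is required")
  }
  a <- SummarizedExperiment::assay(object, "density")
  if (anyNA(a)) msg <- c(msg, "densities must not contain missing values")
  if (nrow(a) > 0 && ncol(a) > 2 && !anyNA(a)) {
    mu <- rowMeans(a)
    sds <- apply(a, 1, stats::sd)
    if (any(abs(mu) > 1e-9) || any(abs(sds - 1) > 1e-9)) {
      msg <- c(msg, "each receptor map must be z-scored (mean 0, sd 1, tol 1e-9)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SpinEnsemble: rotated-parcel reassignments for the spin test
#'
#' Each row of `assignments` realizes one random rotation of the spherical
#' parcel coordinates (applied to the left hemisphere, with its x-mirrored
#' conjugate applied to the right): entry `[p, i]` is the index of the source
#' parcel whose value parcel `i` receives under rotation `p`. Rows need not
#' be permutations; several targets may receive the same source when the
#' nearest rotated parcel coincides. Indices never cross hemispheres.
#'
#' @slot assignments integer matrix, `nPerm` x n regions.
#' @slot seed integer seed the ensemble was generated from.
#' @slot hemisphere hemisphere label per region (for validity checks).
#'
#' @seealso [buildSpinEnsemble()], [spinPvalue()]
#' @export
setClass("SpinEnsemble",
  representation(assignments = "matrix", seed = "integer",
                 hemisphere = "character")
)

setValidity("SpinEnsemble", function(object) {
  a <- object@assignments
  n <- ncol(a)
  msg <- character(0)
  if (!is.numeric(a) || n < 1 || nrow(a) < 1) {
    return("assignments must be a non-empty integer matrix")
  }
  if (any(a < 1) || any(a > n)) msg <- c(msg, "assignment indices out of range")
  if (length(object@hemisphere) == n) {
    hm <- matrix(object@hemisphere[a], nrow(a), n)
    tgt <- matrix(object@hemisphere, nrow(a), n, byrow = TRUE)
    if (any(hm != tgt)) msg <- c(msg, "assignments must respect hemispheres")
  }
  if (length(msg)) msg else TRUE
})

#' RewiredEnsemble: length-binned degree-preserving connectome nulls
#'
#' Null structural connectomes obtained by double-edge swaps restricted to
#' edges of similar Euclidean length (same distance bin). Every null
#' preserves exactly the edge count, the binary degree sequence and the
#' per-bin edge counts of the empirical network; edge weights travel with
#' their edges.
#'
#' @slot matrices list of null connectivity matrices.
#' @slot binEdges numeric vector of distance-bin boundaries, mm.
#' @slot nSwaps integer vector, accepted swaps per null.
#' @slot seed integer seed.
#'
#' @seealso [rewirePreservingLength()], [connectedContrastTest()]
#' @export
setClass("RewiredEnsemble",
  representation(matrices = "list", binEdges = "numeric",
                 nSwaps = "integer", seed = "integer")
)

#' DecayFit: exponential distance-decay fit
#'
#' Least-squares fit of `similarity = a * exp(-b * distance) + c` over
#' region pairs.
#'
#' @slot amplitude fitted `a`.
#' @slot rate fitted decay rate `b` (1/mm), constrained non-negative.
#' @slot offset fitted asymptote `c`.
#' @slot rss residual sum of squares.
#' @slot nPairs number of region pairs entering the fit.
#' @export
setClass("DecayFit",
  representation(amplitude = "numeric", rate = "numeric", offset = "numeric",
                 rss = "numeric", nPairs = "integer")
)

setValidity("DecayFit", function(object) {
  if (length(object@rate) == 1 && is.finite(object@rate) && object@rate < 0) {
    "rate must be non-negative"
  } else TRUE
})

#' MultilinearResult: multilinear regression of a regional map on the atlas
#'
#' @slot coefficients named coefficients (intercept first).
#' @slot r2 coefficient of determination.
#' @slot r2adj adjusted R squared, `1 - (1 - r2) (n-1)/(n-p-1)`.
#' @slot pSpin spin-test model significance (NA until assessed).
#' @slot n number of regions fit.
#' @export
setClass("MultilinearResult",
  representation(coefficients = "numeric", r2 = "numeric", r2adj = "numeric",
                 pSpin = "numeric", n = "integer")
)

setValidity("MultilinearResult", function(object) {
  msg <- character(0)
  if (object@r2 < -1e-10 || object@r2 > 1 + 1e-10) {
    msg <- c(msg, "r2 must lie in [0, 1]")
  }
  if (object@r2adj > object@r2 + 1e-10) msg <- c(msg, "r2adj must not exceed r2")
  if (length(msg)) msg else TRUE
})

#' DominanceResult: full-subset dominance decomposition of a model fit
#'
#' Total dominance of predictor k is the average, over subset sizes, of the
#' mean increase in R squared when k joins a submodel, across all 2^p - 1
#' submodels. The totals sum exactly to the full-model R squared; percent
#' shares are reported normalized both by R squared and by adjusted R
#' squared.
#'
#' @slot total named total dominance per predictor (R squared units).
#' @slot percent share of full-model R squared, percent.
#' @slot percentAdj share of full-model adjusted R squared, percent.
#' @slot r2full full-model R squared.
#' @slot r2adjFull full-model adjusted R squared.
#' @slot classAggregates data.frame of mean percent by predictor class
#'   (0 rows when no classes were supplied).
#' @export
setClass("DominanceResult",
  representation(total = "numeric", percent = "numeric",
                 percentAdj = "numeric", r2full = "numeric",
                 r2adjFull = "numeric", classAggregates = "data.frame")
)

setValidity("DominanceResult", function(object) {
  msg <- character(0)
  if (any(object@total < -1e-8)) msg <- c(msg, "total dominance must be >= 0")
  if (abs(sum(object@total) - object@r2full) > 1e-8) {
    msg <- c(msg, "total dominance must sum to the full-model R squared")
  }
  if (object@r2full > 1e-12 &&
      abs(sum(object@percent) - 100) > 1e-6) {
    msg <- c(msg, "percent shares must sum to 100")
  }
  if (length(msg)) msg else TRUE
})

#' CVResult: distance-dependent cross-validation result
#'
#' One fold per region: the source's nearest 75% of regions (source
#' included) train the model and the remaining 25% test it.
#'
#' @slot sourceIds region label of each fold's source node.
#' @slot trainR in-sample Pearson correlation per fold.
#' @slot testR out-of-sample Pearson correlation per fold.
#' @slot meanTestR mean out-of-sample correlation.
#' @slot pNull permutation p-value for `meanTestR` (NA when no null run).
#' @export
setClass("CVResult",
  representation(sourceIds = "character", trainR = "numeric",
                 testR = "numeric", meanTestR = "numeric", pNull = "numeric")
)

setValidity("CVResult", function(object) {
  r <- c(object@trainR, object@testR)
  r <- r[is.finite(r)]
  if (length(r) && (min(r) < -1 - 1e-8 || max(r) > 1 + 1e-8)) {
    "correlations must lie in [-1, 1]"
  } else TRUE
})

#' PLSResult: PLS-correlation decomposition of two regional data blocks
#'
#' Singular value decomposition of the cross-covariance between a z-scored
#' region x receptor block and a z-scored region x feature block. Scores are
#' the data projected onto the singular vectors; loadings are Pearson
#' correlations between original columns and scores.
#'
#' @slot xWeights,yWeights orthonormal singular vector matrices.
#' @slot singularValues singular values of the cross-covariance.
#' @slot covExplained fraction of squared cross-covariance per latent
#'   variable (non-increasing, sums to 1).
#' @slot xScores,yScores region score matrices (one column per LV).
#' @slot xLoadings,yLoadings feature-score correlations per LV.
#' @slot pSpin spin p-value per LV (NA until assessed).
#' @export
setClass("PLSResult",
  representation(xWeights = "matrix", yWeights = "matrix",
                 singularValues = "numeric", covExplained = "numeric",
                 xScores = "matrix", yScores = "matrix",
                 xLoadings = "matrix", yLoadings = "matrix",
                 pSpin = "numeric")
)

setValidity("PLSResult", function(object) {
  msg <- character(0)
  for (w in list(object@xWeights, object@yWeights)) {
    g <- crossprod(w)
    if (max(abs(g - diag(ncol(w)))) > 1e-9) {
      msg <- c(msg, "weight matrices must be orthonormal (tol 1e-9)")
      break
    }
  }
  ce <- object@covExplained
  if (abs(sum(ce) - 1) > 1e-9) msg <- c(msg, "covExplained must sum to 1")
  if (is.unsorted(rev(ce), strictly = FALSE)) {
    msg <- c(msg, "covExplained must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' CouplingResult: receptor-augmented structure-function coupling
#'
#' Per-region adjusted R squared of functional connectivity regressed on
#' communicability alone (`r2Base`) and with the region's receptor
#' similarity profile added (`r2Augmented`), with one-sided spin p-values
#' and BH-FDR flags for the augmentation.
#'
#' @slot regionIds region labels.
#' @slot r2Base,r2Augmented adjusted R squared per region.
#' @slot delta `r2Augmented - r2Base`.
#' @slot pSpin one-sided spin p-value per region.
#' @slot pAdjusted BH-adjusted p-values.
#' @slot significant logical FDR flags.
#' @export
setClass("CouplingResult",
  representation(regionIds = "character", r2Base = "numeric",
                 r2Augmented = "numeric", delta = "numeric",
                 pSpin = "numeric", pAdjusted = "numeric",
                 significant = "logical")
)

setValidity("CouplingResult", function(object) {
  msg <- character(0)
  if (any(!is.finite(object@delta))) msg <- c(msg, "delta must be finite")
  p <- object@pSpin[is.finite(object@pSpin)]
  if (length(p) && (min(p) <= 0 || max(p) > 1)) {
    msg <- c(msg, "pSpin must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})
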
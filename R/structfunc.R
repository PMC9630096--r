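#' Weighted network communicability
#'
#' Communicability sums the contributions of all walks between two regions,
#' each walk down-weighted by the factorial of its length: the matrix
#' exponential of the strength-normalized adjacency
#' `S^(-1/2) A S^(-1/2)` (S the diagonal matrix of node strengths). The
#' normalization keeps the exponential from being dominated by the overall
#' weight scale.
#'
#' @param sc symmetric non-negative structural connectome, zero diagonal.
#' @return Symmetric region x region communicability matrix. An all-zero
#'   input returns the identity (`expm(0) = I`); an isolated region (zero
#'   strength) is an error naming the region.
#' @export
communicability <- function(sc) {
  .checkSquareSymmetric(sc, "sc")
  if (any(sc < 0)) stop("structural weights must be >= 0", call. = FALSE)
  n <- nrow(sc)
  if (all(sc == 0)) {
    out <- diag(n)
    dimnames(out) <- dimnames(sc)
    return(out)
  }
  s <- rowSums(sc)
  if (any(s == 0)) {
    bad <- which(s == 0)[1]
    nm <- if (!is.null(rownames(sc))) rownames(sc)[bad] else bad
    stop("isolated region with zero strength: ", nm, call. = FALSE)
  }
  inv <- 1 / sqrt(s)
  m <- sc * tcrossprod(inv)
  out <- as.matrix(Matrix::expm(Matrix::Matrix(m)))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(sc)
  out
}

#' Residualize edge values on Euclidean distance
#'
#' Vectorizes the upper triangle of a symmetric matrix and returns the OLS
#' residuals (intercept included) of the edge values on the corresponding
#' centroid distances. Residuals are exactly orthogonal to distance.
#'
#' @param matrix symmetric region x region matrix of edge values.
#' @param geometry matching [ParcelGeometry-class].
#' @return Numeric vector of residualized upper-triangle edge values.
#' @export
residualizeEdges <- function(matrix, geometry) {
  .checkSquareSymmetric(matrix, "matrix")
  x <- .upperTri(matrix)
  d <- .upperTri(distanceMatrix(geometry))
  .residOnDistance(x, d)
}

.residOnDistance <- function(x, d) {
  if (stats::sd(d) < 1e-12) stop("constant distances", call. = FALSE)
  stats::lsfit(d, x)$residuals
}

#' Distance-regressed edge correlation between two modalities
#'
#' Correlates the upper triangles of two symmetric matrices after removing
#' the linear effect of Euclidean distance from each (the residualization is
#' performed on the selected edge set). `restrict = "connected_only"`
#' limits the comparison to edges present in the structural connectome.
#'
#' @param xMatrix,yMatrix symmetric region x region matrices.
#' @param geometry matching [ParcelGeometry-class].
#' @param restrict `"all"` edges or `"connected_only"`.
#' @param sc structural connectome (required for `"connected_only"`).
#' @return A list with `r` (Pearson correlation of residualized edges) and
#'   `nEdges`.
#' @export
edgeCorrelation <- function(xMatrix, yMatrix, geometry,
                            restrict = c("all", "connected_only"),
                            sc = NULL) {
  restrict <- match.arg(restrict)
  .checkSquareSymmetric(xMatrix, "xMatrix")
  .checkSquareSymmetric(yMatrix, "yMatrix")
  if (any(dim(xMatrix) != dim(yMatrix))) {
    stop("matrices must have matching shapes", call. = FALSE)
  }
  x <- .upperTri(xMatrix)
  y <- .upperTri(yMatrix)
  d <- .upperTri(distanceMatrix(geometry))
  if (restrict == "connected_only") {
    if (is.null(sc)) stop("sc required for connected_only", call. = FALSE)
    keep <- .upperTri(sc) > 0
    x <- x[keep]; y <- y[keep]; d <- d[keep]
  }
  if (length(x) < 3) stop("fewer than 3 edges after restriction",
                          call. = FALSE)
  xr <- .residOnDistance(x, d)
  yr <- .residOnDistance(y, d)
  list(r = stats::cor(xr, yr), nEdges = length(x))
}

#' Regional structure-function coupling
#'
#' For each region, the adjusted R squared of a simple linear regression of
#' its functional connectivity profile (FC to every other region) on its
#' communicability profile, self-connection excluded, intercept included
#' (n - 1 observations, 1 predictor).
#'
#' @param comm communicability matrix.
#' @param fc functional connectivity matrix, matching shape.
#' @return Named numeric vector of adjusted R squared per region; a region
#'   with a zero-variance communicability profile yields `NaN` with a
#'   notice.
#' @export
regionalCoupling <- function(comm, fc) {
  .checkSquareSymmetric(comm, "comm")
  .checkSquareSymmetric(fc, "fc")
  if (any(dim(comm) != dim(fc))) stop("shape mismatch", call. = FALSE)
  n <- nrow(comm)
  out <- vapply(seq_len(n), function(i) {
    x <- comm[i, -i]
    y <- fc[i, -i]
    if (stats::sd(x) < 1e-14) return(NaN)
    r2 <- stats::cor(x, y)^2
    .adjR2(r2, n - 1, 1)
  }, numeric(1))
  if (anyNA(out)) {
    message(sum(is.na(out)), " region(s) with zero-variance predictor ",
            "profile flagged NaN")
  }
  names(out) <- rownames(comm)
  out
}

#' Receptor-augmented structure-function coupling
#'
#' Adds the region's receptor similarity profile as a second predictor to
#' the regional coupling regression and tests, one-sided, whether the
#' augmented adjusted R squared exceeds what a spatially rotated similarity
#' profile achieves. For each region the null distribution is the augmented
#' adjusted R squared recomputed with the similarity row spun by each
#' rotation of the ensemble; p-values are BH-FDR-corrected across regions.
#'
#' @param comm communicability matrix.
#' @param fc functional connectivity matrix.
#' @param similarity receptor similarity matrix.
#' @param spins a [SpinEnsemble-class] built on the same geometry.
#' @param q FDR level (default 0.05).
#' @return A [CouplingResult-class].
#' @export
augmentedCoupling <- function(comm, fc, similarity, spins, q = 0.05) {
  .checkSquareSymmetric(comm, "comm")
  .checkSquareSymmetric(fc, "fc")
  .checkSquareSymmetric(similarity, "similarity")
  n <- nrow(comm)
  asn <- assignments(spins)
  if (ncol(asn) != n) stop("spin ensemble does not match matrices",
                           call. = FALSE)
  nPerm <- nrow(asn)

  r2Base <- numeric(n)
  r2Aug <- numeric(n)
  pSpin <- numeric(n)
  nObs <- n - 1
  for (i in seq_len(n)) {
    y <- fc[i, -i]
    x1 <- comm[i, -i]
    ry1 <- stats::cor(x1, y)
    r2Base[i] <- .adjR2(ry1^2, nObs, 1)

    simRow <- similarity[i, ]
    x2 <- simRow[-i]
    obs <- .augR2(y, x1, x2, ry1, nObs)

    # Spun similarity rows for every rotation at once: entry [p, j] is the
    # similarity value region j receives under rotation p; target i dropped.
    spun <- matrix(simRow[asn], nPerm, n)[, -i, drop = FALSE]
    nullR2 <- .augR2Matrix(y, x1, spun, ry1, nObs)
    r2Aug[i] <- obs
    pSpin[i] <- (1 + sum(nullR2 >= obs)) / (1 + nPerm)
  }
  fdr <- fdrCorrect(pSpin, q)
  ids <- rownames(comm)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  new("CouplingResult", regionIds = ids, r2Base = r2Base,
      r2Augmented = r2Aug, delta = r2Aug - r2Base, pSpin = pSpin,
      pAdjusted = fdr$adjusted, significant = fdr$rejected)
}

# Adjusted R^2 of y on {x1, x2} from pairwise correlations.
.augR2 <- function(y, x1, x2, ry1, nObs) {
  if (stats::sd(x2) < 1e-14) return(.adjR2(ry1^2, nObs, 2))
  r2 <- .r2TwoPredictors(ry1, stats::cor(x2, y), stats::cor(x1, x2))
  .adjR2(r2, nObs, 2)
}

# Vectorized version: rows of `xs` are alternative second predictors.
.augR2Matrix <- function(y, x1, xs, ry1, nObs) {
  mu <- rowMeans(xs)
  sds <- sqrt(pmax(rowSums((xs - mu)^2) / (ncol(xs) - 1), 0))
  ok <- sds > 1e-14
  ry2 <- numeric(nrow(xs))
  r12 <- numeric(nrow(xs))
  ys <- (y - mean(y)) / stats::sd(y)
  x1s <- (x1 - mean(x1)) / stats::sd(x1)
  centered <- xs - mu
  denom <- sds * (ncol(xs) - 1)
  ry2[ok] <- (centered[ok, , drop = FALSE] %*% ys)[, 1] / denom[ok]
  r12[ok] <- (centered[ok, , drop = FALSE] %*% x1s)[, 1] / denom[ok]
  r2 <- .r2TwoPredictors(ry1, ry2, r12)
  r2[!ok] <- ry1^2
  .adjR2(r2, nObs, 2)
}
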
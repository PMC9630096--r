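#' PLS-correlation decomposition of two regional data blocks
#'
#' Singular value decomposition of the cross-covariance matrix
#' `X'Y / (n - 1)` between two column-z-scored region x feature blocks
#' (receptor densities and, e.g., term-activation maps). Each latent
#' variable pairs an X weight vector with a Y weight vector; its squared
#' singular value, as a fraction of the total, is the covariance it
#' explains. Scores are the data projected onto the weights; loadings are
#' Pearson correlations between original columns and scores. The sign of
#' each latent variable is fixed so that its X score correlates positively
#' with the regional mean of X.
#'
#' @param X regions x receptors matrix (or a [ReceptorAtlas-class]),
#'   columns z-scored.
#' @param Y regions x features matrix, columns z-scored.
#' @return A [PLSResult-class]. An (effectively) all-zero cross-covariance
#'   is an error.
#' @export
plsDecompose <- function(X, Y) {
  X <- .asPredictorMatrix(X)
  Y <- .asPredictorMatrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must share the region dimension",
                               call. = FALSE)
  n <- nrow(X)
  cc <- crossprod(X, Y) / (n - 1)
  if (max(abs(cc)) < 1e-12) stop("cross-covariance matrix is zero",
                                 call. = FALSE)
  sv <- svd(cc)
  u <- sv$u
  v <- sv$v
  xScores <- X %*% u
  refMap <- rowMeans(X)
  for (k in seq_along(sv$d)) {
    if (stats::sd(refMap) > 1e-14 && stats::sd(xScores[, k]) > 1e-14 &&
        stats::cor(xScores[, k], refMap) < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
      xScores[, k] <- -xScores[, k]
    }
  }
  yScores <- Y %*% v
  colnames(u) <- colnames(v) <- colnames(xScores) <- colnames(yScores) <-
    paste0("LV", seq_along(sv$d))
  rownames(u) <- colnames(X)
  rownames(v) <- colnames(Y)
  new("PLSResult",
      xWeights = u, yWeights = v, singularValues = sv$d,
      covExplained = sv$d^2 / sum(sv$d^2),
      xScores = xScores, yScores = yScores,
      xLoadings = plsLoadings(X, xScores),
      yLoadings = plsLoadings(Y, yScores),
      pSpin = rep(NA_real_, length(sv$d)))
}

#' Spin-test significance of PLS latent variables
#'
#' Rotates the rows of the X block by every spin of the ensemble,
#' re-decomposes, and compares each observed singular value one-sided
#' against its null counterparts (k-th observed vs k-th null singular
#' value; no Procrustes alignment — significance is assessed on the
#' singular values alone).
#'
#' @param X regions x receptors matrix (or a [ReceptorAtlas-class]).
#' @param Y regions x features matrix.
#' @param spins a [SpinEnsemble-class] on the same parcellation.
#' @return A list with `p` (one per latent variable), `observed` singular
#'   values and the `nullSingularValues` matrix (spins x LV).
#' @export
plsSignificance <- function(X, Y, spins) {
  X <- .asPredictorMatrix(X)
  Y <- .asPredictorMatrix(Y)
  res <- plsDecompose(X, Y)
  d <- singularValues(res)
  asn <- assignments(spins)
  if (ncol(asn) != nrow(X)) stop("spin ensemble does not match X",
                                 call. = FALSE)
  n <- nrow(X)
  nullD <- t(vapply(seq_len(nrow(asn)), function(p) {
    svd(crossprod(X[asn[p, ], , drop = FALSE], Y) / (n - 1),
        nu = 0, nv = 0)$d
  }, numeric(length(d))))
  p <- vapply(seq_along(d), function(k) {
    spinPvalue(d[k], nullD[, k], "one_greater")
  }, numeric(1))
  names(p) <- paste0("LV", seq_along(d))
  list(p = p, observed = d, nullSingularValues = nullD)
}

#' Feature loadings on PLS scores
#'
#' Pearson correlation between each column of a data block and each score
#' vector; a zero-variance column yields `NA` with a warning.
#'
#' @param data regions x features matrix.
#' @param scores regions x LV score matrix (or a single score vector).
#' @return features x LV matrix of loadings.
#' @export
plsLoadings <- function(data, scores) {
  data <- .asPredictorMatrix(data)
  scores <- as.matrix(scores)
  sds <- apply(data, 2, stats::sd)
  out <- matrix(NA_real_, ncol(data), ncol(scores),
                dimnames = list(colnames(data), colnames(scores)))
  ok <- sds > 1e-14
  if (any(!ok)) warning("zero-variance column(s): loadings set NA",
                        call. = FALSE)
  out[ok, ] <- stats::cor(data[, ok, drop = FALSE], scores)
  out
}

#' Distance-dependent cross-validation of the PLS correlation
#'
#' One fold per region: the source's nearest `trainFrac` of regions train
#' the decomposition; the first latent variable's weights are then applied
#' to the held-out regions (centered by training means), and the
#' correlation between X and Y scores is recorded separately in the
#' training and test sets. When a spin ensemble is supplied, the mean test
#' correlation is compared one-sided to the same procedure run on spun X
#' blocks.
#'
#' @param X regions x receptors matrix (or a [ReceptorAtlas-class]).
#' @param Y regions x features matrix.
#' @param geometry matching [ParcelGeometry-class].
#' @param trainFrac training fraction (default 0.75).
#' @param spins optional [SpinEnsemble-class] for the permuted null.
#' @return A [CVResult-class].
#' @export
plsDistanceCV <- function(X, Y, geometry, trainFrac = 0.75, spins = NULL) {
  X <- .asPredictorMatrix(X)
  Y <- .asPredictorMatrix(Y)
  n <- nrow(X)
  d <- distanceMatrix(geometry)
  if (nrow(d) != n) stop("geometry does not match X", call. = FALSE)
  nTrain <- ceiling(trainFrac * n)
  if (n - nTrain < 3) stop("test sets would have fewer than 3 regions",
                           call. = FALSE)
  folds <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    list(train = ord[seq_len(nTrain)], test = ord[(nTrain + 1):n])
  })
  run <- function(Xb) {
    vapply(folds, function(f) {
      Xt <- Xb[f$train, , drop = FALSE]
      Yt <- Y[f$train, , drop = FALSE]
      mx <- colMeans(Xt)
      my <- colMeans(Yt)
      Xc <- sweep(Xt, 2, mx)
      Yc <- sweep(Yt, 2, my)
      sv <- svd(crossprod(Xc, Yc) / (nrow(Xc) - 1), nu = 1, nv = 1)
      u <- sv$u[, 1]
      v <- sv$v[, 1]
      xsTrain <- Xc %*% u
      if (stats::sd(rowMeans(Xc)) > 1e-14 && stats::sd(xsTrain) > 1e-14 &&
          stats::cor(xsTrain, rowMeans(Xc)) < 0) {
        u <- -u; v <- -v; xsTrain <- -xsTrain
      }
      ysTrain <- Yc %*% v
      xsTest <- sweep(Xb[f$test, , drop = FALSE], 2, mx) %*% u
      ysTest <- sweep(Y[f$test, , drop = FALSE], 2, my) %*% v
      c(trainR = stats::cor(xsTrain, ysTrain),
        testR = stats::cor(xsTest, ysTest))
    }, numeric(2))
  }
  obs <- run(X)
  meanTest <- mean(obs["testR", ], na.rm = TRUE)
  pNull <- NA_real_
  if (!is.null(spins)) {
    asn <- assignments(spins)
    nullMeans <- vapply(seq_len(nrow(asn)), function(pp) {
      mean(run(X[asn[pp, ], , drop = FALSE])["testR", ], na.rm = TRUE)
    }, numeric(1))
    pNull <- spinPvalue(meanTest, nullMeans, "one_greater")
  }
  new("CVResult", sourceIds = regionIds(geometry),
      trainR = unname(obs["trainR", ]), testR = unname(obs["testR", ]),
      meanTestR = meanTest, pNull = pNull)
}
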
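#' @useDynLib chemoarch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Multilinear regression of a regional map on receptor densities
#'
#' Ordinary least squares with intercept of a regional map on the full
#' region x receptor matrix; reports R squared and adjusted R squared
#' (`1 - (1 - R2) (n - 1) / (n - p - 1)`).
#'
#' @param X regions x predictors matrix (or a [ReceptorAtlas-class]).
#' @param y numeric region map.
#' @return A [MultilinearResult-class]. Rank-deficient design is an error
#'   listing the collinear columns.
#' @export
fitMultilinear <- function(X, y) {
  X <- .asPredictorMatrix(X)
  y <- as.vector(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("y must have one value per region", call. = FALSE)
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  if (n <= p + 1) stop("need more regions than predictors + 1", call. = FALSE)
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrd, y)
  res <- qr.resid(qrd, y)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  new("MultilinearResult", coefficients = coefs, r2 = r2,
      r2adj = .adjR2(r2, n, p), pSpin = NA_real_, n = as.integer(n))
}

.asPredictorMatrix <- function(X) {
  if (is(X, "ReceptorAtlas")) X <- densities(X)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Spin-test significance of a multilinear model
#'
#' Refits the model with the outcome map spun by every rotation of the
#' ensemble and reports the one-sided p-value of the observed adjusted R
#' squared against the null adjusted R squared distribution. When several
#' maps are tested together, correct the returned p-values with
#' [fdrCorrect()].
#'
#' @param X regions x predictors matrix (or a [ReceptorAtlas-class]).
#' @param y numeric region map.
#' @param spins a [SpinEnsemble-class] on the same parcellation.
#' @return A list with `p`, `observed` (adjusted R squared) and
#'   `nullR2adj`.
#' @export
spinModelSignificance <- function(X, y, spins) {
  X <- .asPredictorMatrix(X)
  asn <- assignments(spins)
  if (nrow(asn) < 1) stop("empty spin ensemble", call. = FALSE)
  if (ncol(asn) != nrow(X)) stop("spin ensemble does not match X",
                                 call. = FALSE)
  fit <- fitMultilinear(X, y)
  n <- nrow(X)
  p <- ncol(X)
  design <- cbind(1, X)
  qrd <- qr(design)
  yNull <- matrix(y[t(asn)], n, nrow(asn))
  res <- qr.resid(qrd, yNull)
  tss <- colSums(sweep(yNull, 2, colMeans(yNull))^2)
  r2 <- 1 - colSums(res^2) / tss
  nullR2adj <- .adjR2(r2, n, p)
  list(p = spinPvalue(fit@r2adj, nullR2adj, "one_greater"),
       observed = fit@r2adj, nullR2adj = nullR2adj)
}

#' Dominance analysis of a multilinear model
#'
#' Decomposes the full-model R squared into per-predictor contributions by
#' fitting every one of the 2^p - 1 predictor subsets (enumerated from a
#' single precomputed cross-product matrix in compiled code). The total
#' dominance of a predictor is the average over subset sizes of its mean
#' incremental R squared; totals sum exactly to the full-model R squared.
#' Percent shares are reported normalized by R squared and, for reporting
#' parity with adjusted-fit conventions, by adjusted R squared.
#'
#' @param X regions x predictors matrix (or a [ReceptorAtlas-class]).
#' @param y numeric region map.
#' @param classes optional factor of predictor classes; mean percent share
#'   per class is aggregated when given.
#' @param maxP guard on the exhaustive enumeration (default 20).
#' @return A [DominanceResult-class].
#' @export
dominance <- function(X, y, classes = NULL, maxP = 20) {
  X <- .asPredictorMatrix(X)
  p <- ncol(X)
  if (p > maxP) {
    stop("p = ", p, " exceeds the enumeration guard (", maxP,
         "); select a predictor subset", call. = FALSE)
  }
  # The subset enumeration handles collinear (even duplicated) predictor
  # sets through pseudo-inverse solves, so no rank pre-check here.
  z <- scale(X)
  if (any(attr(z, "scaled:scale") == 0)) {
    stop("zero-variance predictor column", call. = FALSE)
  }
  yz <- .zscore(as.vector(y), "outcome")
  n <- nrow(X)
  R <- crossprod(z) / (n - 1)
  ry <- crossprod(z, yz)[, 1] / (n - 1)
  core <- .dominanceCore(R, ry)
  total <- core$total
  names(total) <- colnames(X)
  r2full <- core$r2full
  r2adjFull <- .adjR2(r2full, n, p)
  percent <- if (r2full > 1e-12) 100 * total / r2full else total * 0
  percentAdj <- if (abs(r2adjFull) > 1e-12) 100 * total / r2adjFull
                else total * 0
  agg <- if (!is.null(classes)) {
    cl <- as.factor(classes)
    data.frame(class = levels(cl),
               meanPercent = as.vector(tapply(percent, cl, mean)),
               totalPercent = as.vector(tapply(percent, cl, sum)))
  } else {
    data.frame(class = character(0), meanPercent = numeric(0),
               totalPercent = numeric(0))
  }
  new("DominanceResult", total = total, percent = percent,
      percentAdj = percentAdj, r2full = r2full, r2adjFull = r2adjFull,
      classAggregates = agg)
}

#' Distance-dependent cross-validation of a multilinear model
#'
#' Each region serves once as the source node: the `trainFrac` fraction of
#' regions nearest the source (source included) form the training set and
#' the remainder the test set, limiting spatial leakage between the two.
#' The model is fit on the training regions and the Pearson correlation
#' between predicted and observed test values is recorded per fold. When a
#' spin ensemble is supplied, the mean test correlation is compared
#' one-sided against the same cross-validation run on spun outcome maps.
#'
#' @param X regions x predictors matrix (or a [ReceptorAtlas-class]).
#' @param y numeric region map.
#' @param geometry matching [ParcelGeometry-class].
#' @param trainFrac fraction of regions in each training set (default
#'   0.75).
#' @param spins optional [SpinEnsemble-class] for the permuted null.
#' @return A [CVResult-class] with one fold per region.
#' @export
distanceCV <- function(X, y, geometry, trainFrac = 0.75, spins = NULL) {
  X <- .asPredictorMatrix(X)
  n <- nrow(X)
  d <- distanceMatrix(geometry)
  if (nrow(d) != n) stop("geometry does not match X", call. = FALSE)
  nTrain <- ceiling(trainFrac * n)
  if (n - nTrain < 3) stop("test sets would have fewer than 3 regions",
                           call. = FALSE)
  folds <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ])          # source itself first (distance 0)
    list(train = ord[seq_len(nTrain)], test = ord[(nTrain + 1):n])
  })
  run <- function(yy) {
    vapply(folds, function(f) {
      fitTrain <- stats::lsfit(X[f$train, , drop = FALSE], yy[f$train])
      pred <- cbind(1, X[f$test, , drop = FALSE]) %*% fitTrain$coefficients
      if (stats::sd(pred) < 1e-14 || stats::sd(yy[f$test]) < 1e-14) {
        return(c(trainR = NA_real_, testR = NA_real_))
      }
      c(trainR = stats::cor(cbind(1, X[f$train, , drop = FALSE]) %*%
                              fitTrain$coefficients, yy[f$train]),
        testR = stats::cor(pred, yy[f$test]))
    }, numeric(2))
  }
  obs <- run(y)
  meanTest <- mean(obs["testR", ], na.rm = TRUE)
  pNull <- NA_real_
  if (!is.null(spins)) {
    asn <- assignments(spins)
    nullMeans <- vapply(seq_len(nrow(asn)), function(pp) {
      mean(run(y[asn[pp, ]])["testR", ], na.rm = TRUE)
    }, numeric(1))
    pNull <- spinPvalue(meanTest, nullMeans, "one_greater")
  }
  new("CVResult", sourceIds = regionIds(geometry),
      trainR = unname(obs["trainR", ]), testR = unname(obs["testR", ]),
      meanTestR = meanTest, pNull = pNull)
}
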
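# Internal numerical helpers shared across modules.

# z-score with sample sd (ddof = 1); errors on zero variance so degenerate
# inputs surface early instead of propagating NaN.
.zscore <- function(x, label = "input") {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps * max(1, abs(mean(x))) * 10 ||
      s == 0) {
    stop("zero-variance ", label, ": cannot z-score", call. = FALSE)
  }
  (x - mean(x)) / s
}

.zscoreCols <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) {
    out[, j] <- .zscore(m[, j], label = paste0("column ", j))
  }
  out
}

.upperTri <- function(m) m[upper.tri(m)]

# Fan a single user seed out into independent substreams, all < 2^31.
.subSeeds <- function(seed, n) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restoreRNG <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Run code under a given seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  expr
}

# Rotation drawn uniformly from SO(3): QR of a Gaussian matrix with the sign
# of R's diagonal absorbed into Q, determinant forced to +1.
.randomRotation <- function() {
  repeat {
    m <- matrix(stats::rnorm(9), 3, 3)
    qrm <- qr(m)
    q <- qr.Q(qrm)
    d <- sign(diag(qr.R(qrm)))
    d[d == 0] <- 1
    q <- q %*% diag(d)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    if (abs(det(q) - 1) < 1e-8) return(q)
  }
}

.checkSquareSymmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(name, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(name, " must be symmetric (tolerance ", tol, ")", call. = FALSE)
  }
  invisible(TRUE)
}

# Adjusted R^2 for OLS with intercept.
.adjR2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

# R^2 of y on two standardized predictors from pairwise correlations.
# Degenerate (collinear) pairs fall back to the single-predictor fit.
.r2TwoPredictors <- function(ry1, ry2, r12) {
  denom <- 1 - r12^2
  r2 <- (ry1^2 + ry2^2 - 2 * ry1 * ry2 * r12) / denom
  bad <- !is.finite(r2) | denom < 1e-12
  if (any(bad)) r2[bad] <- pmax(ry1[bad]^2, ry2[bad]^2)
  pmin(r2, 1)
}
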
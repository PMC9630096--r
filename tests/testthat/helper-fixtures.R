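# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, maker(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

geom100 <- function() fixture("geom100", function() {
  generateParcellation(100, seed = 1)
})

geom60 <- function() fixture("geom60", function() {
  generateParcellation(60, seed = 3)
})

spins1000 <- function() fixture("spins1000", function() {
  buildSpinEnsemble(geom100(), 1000, seed = 42)
})

spins300 <- function() fixture("spins300", function() {
  buildSpinEnsemble(geom100(), 300, seed = 7)
})

atlas19 <- function() fixture("atlas19", function() {
  generateReceptorAtlas(geom100(), 19, nLatent = 3, noiseSd = 0.2, seed = 2)
})

# Exponential-covariance Cholesky factor for fast repeated SA draws.
saFactor <- function() fixture("saFactor", function() {
  chemoarch:::.saMapFactor(geom100(), lengthScale = 20, sigma = 1)
})

drawSAMaps <- function(nDraws, seed) {
  u <- saFactor()
  set.seed(seed)
  matrix(stats::rnorm(nDraws * ncol(u)), nDraws) %*% u
}

# Naive dominance oracle: refit every subset with lm.
dominanceOracle <- function(X, y) {
  p <- ncol(X)
  r2 <- function(S) {
    if (!length(S)) return(0)
    summary(stats::lm(y ~ X[, S, drop = FALSE]))$r.squared
  }
  vapply(seq_len(p), function(k) {
    others <- setdiff(seq_len(p), k)
    bySize <- vapply(0:(p - 1), function(s) {
      # index through positions: combn(scalar, ...) would expand to 1:scalar
      subs <- lapply(utils::combn(length(others), s, simplify = FALSE),
                     function(ix) others[ix])
      mean(vapply(subs, function(S) r2(c(S, k)) - r2(S), numeric(1)))
    }, numeric(1))
    mean(bySize)
  }, numeric(1))
}

# Distance-weighted Moran-style autocorrelation, within-hemisphere pairs
# only (hemisphere-separate spins preserve only within-hemisphere
# structure).
moranWithinHemisphere <- function(v, geometry) {
  d <- distanceMatrix(geometry)
  n <- nrow(d)
  w <- 1 / (d + diag(n))
  diag(w) <- 0
  h <- hemispheres(geometry)
  w[outer(h, h, "!=")] <- 0
  v <- v - mean(v)
  n / sum(w) * sum(w * outer(v, v)) / sum(v^2)
}
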
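test_that("communicability matches closed forms and the walk series", {
  expect_equal(communicability(matrix(0, 4, 4)), diag(4))

  # two nodes, one edge: normalized adjacency has unit off-diagonal
  two <- matrix(c(0, 0.37, 0.37, 0), 2, 2)
  expect_equal(communicability(two),
               matrix(c(cosh(1), sinh(1), sinh(1), cosh(1)), 2, 2),
               tolerance = 1e-12)

  # truncated power-series oracle on a random weighted graph
  set.seed(51)
  n <- 15
  a <- matrix(stats::runif(n * n), n, n) * (matrix(stats::runif(n * n), n, n) < 0.3)
  a <- a + t(a)
  diag(a) <- 0
  a[1, 2] <- a[2, 1] <- a[1, 2] + 0.5   # guard against isolates
  a <- a + 0.01
  diag(a) <- 0
  s <- rowSums(a)
  m <- a / sqrt(outer(s, s))
  series <- diag(n)
  term <- diag(n)
  for (k in 1:30) {
    term <- term %*% m / k
    series <- series + term
  }
  expect_equal(communicability(a), (series + t(series)) / 2,
               tolerance = 1e-8)

  # permutation equivariance
  perm <- sample(n)
  expect_equal(communicability(a[perm, perm]),
               communicability(a)[perm, perm], tolerance = 1e-10)

  iso <- matrix(0, 3, 3)
  iso[1, 2] <- iso[2, 1] <- 1
  rownames(iso) <- colnames(iso) <- c("a", "b", "lonely")
  expect_error(communicability(iso), "lonely")
  expect_error(communicability(matrix(c(0, -1, -1, 0), 2, 2)), ">= 0")
})

test_that("edge residualization removes the distance effect exactly", {
  geom <- geom60()
  d <- distanceMatrix(geom)
  linear <- 3 - 0.01 * d
  diag(linear) <- 0
  expect_lt(max(abs(residualizeEdges(linear, geom))), 1e-10)

  sim <- receptorSimilarity(generateReceptorAtlas(geom, 8, seed = 5)$atlas)
  res <- residualizeEdges(sim, geom)
  expect_lt(abs(stats::cor(res, d[upper.tri(d)])), 1e-10)

  # 4-region arithmetic oracle via lm
  ids <- c("a", "b", "c", "d")
  cent <- rbind(c(-30, 0, 0), c(-20, 5, 0), c(25, 0, 5), c(30, -5, 0))
  rownames(cent) <- ids
  sph <- diag(3)[c(1, 2, 3), ]
  sph <- rbind(sph, c(0, 1, 0))
  rownames(sph) <- ids
  toy <- new("ParcelGeometry", regionIds = ids, centroids = cent,
             sphereCoords = sph,
             hemisphere = c("left", "left", "right", "right"),
             medialWall = matrix(numeric(0), 0, 3),
             distance = as.matrix(stats::dist(cent)))
  vals <- matrix(0, 4, 4)
  vals[upper.tri(vals)] <- c(5, 2, 8, 1, 9, 4)
  vals <- vals + t(vals)
  dd <- distanceMatrix(toy)[upper.tri(vals)]
  oracle <- stats::resid(stats::lm(vals[upper.tri(vals)] ~ dd))
  expect_equal(unname(residualizeEdges(vals, toy)), unname(oracle),
               tolerance = 1e-10)
})

test_that("edge correlation residualizes within the selected edge set", {
  geom <- geom100()
  sim <- receptorSimilarity(atlas19()$atlas)
  self <- edgeCorrelation(sim, sim, geom)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$nEdges, 100 * 99 / 2)

  sc <- generateConnectomes(geom, sim, density = 0.2, seed = 21)$sc
  conn <- edgeCorrelation(sim, sc, geom, restrict = "connected_only",
                          sc = sc)
  expect_equal(conn$nEdges, 990)
  expect_true(abs(conn$r) <= 1)
  expect_error(edgeCorrelation(sim, sc, geom, restrict = "connected_only"),
               "sc required")
})

test_that("regional coupling equals the per-region adjusted R squared", {
  geom <- geom60()
  sim <- receptorSimilarity(generateReceptorAtlas(geom, 8, seed = 6)$atlas)
  cons <- generateConnectomes(geom, sim, density = 0.25, seed = 7)
  comm <- communicability(cons$sc)

  perfect <- 2 * comm + 1
  diag(perfect) <- 0
  expect_equal(unname(regionalCoupling(comm, perfect)), rep(1, 60),
               tolerance = 1e-10)

  # 5-region arithmetic oracle
  set.seed(8)
  c5 <- matrix(stats::rnorm(25), 5, 5)
  c5 <- c5 + t(c5)
  diag(c5) <- 0
  f5 <- matrix(stats::rnorm(25), 5, 5)
  f5 <- f5 + t(f5)
  diag(f5) <- 0
  got <- regionalCoupling(c5, f5)
  oracle <- vapply(1:5, function(i) {
    summary(stats::lm(f5[i, -i] ~ c5[i, -i]))$adj.r.squared
  }, numeric(1))
  expect_equal(unname(got), oracle, tolerance = 1e-10)
})

test_that("coupling of independent FC noise is centred at zero", {
  geom <- geom100()
  sim <- receptorSimilarity(atlas19()$atlas)
  comm <- communicability(generateConnectomes(geom, sim, seed = 22)$sc)
  set.seed(23)
  means <- replicate(50, {
    e <- matrix(stats::rnorm(100 * 100), 100, 100)
    fc <- (e + t(e)) / sqrt(2)
    diag(fc) <- 0
    mean(regionalCoupling(comm, fc))
  })
  expect_lt(abs(mean(means)), 0.02)
})

test_that("a duplicated predictor never raises the augmented fit", {
  geom <- geom60()
  sim <- receptorSimilarity(generateReceptorAtlas(geom, 8, seed = 9)$atlas)
  cons <- generateConnectomes(geom, sim, density = 0.25, couplingBeta = 0.5,
                              noiseSd = 0.1, seed = 10)
  comm <- communicability(cons$sc)
  spins <- buildSpinEnsemble(geom, 50, seed = 11)
  # similarity identical to communicability: the second predictor is
  # perfectly collinear, delta must vanish (adjusted R2 may dip slightly)
  res <- augmentedCoupling(comm, cons$fc, comm, spins)
  base <- regionalCoupling(comm, cons$fc)
  expect_true(all(abs(res@r2Base - base) < 1e-10))
  expect_true(all(res@r2Augmented <= res@r2Base + 1e-8))
  expect_true(all(is.finite(res@delta)))
})

test_that("planted receptor contribution to FC is recovered region-wise", {
  geom <- geom100()
  sim <- receptorSimilarity(atlas19()$atlas)
  spins <- spins300()
  cons <- generateConnectomes(geom, sim, density = 0.2, couplingBeta = 1,
                              noiseSd = 0.1, seed = 24)
  comm <- communicability(cons$sc)
  res <- augmentedCoupling(comm, cons$fc, sim, spins)
  expect_gt(mean(res@significant), 0.8)
  expect_gt(mean(res@delta), 0)

  null <- generateConnectomes(geom, sim, density = 0.2, couplingBeta = 0,
                              noiseSd = 0.1, seed = 25)
  res0 <- augmentedCoupling(communicability(null$sc), null$fc, sim, spins)
  expect_lt(mean(res0@pSpin <= 0.05), 0.15)
})
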
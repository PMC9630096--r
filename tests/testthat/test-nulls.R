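test_that("identity rotation reproduces the input assignment exactly", {
  geom <- geom100()
  row <- chemoarch:::.spinAssignment(geom, diag(3))
  expect_identical(row, seq_len(100))
})

test_that("spin assignments stay within hemispheres and preserve SA", {
  geom <- geom100()
  spins <- spins300()
  asn <- assignments(spins)
  hemi <- hemispheres(geom)
  expect_true(all(matrix(hemi[asn], nrow(asn)) ==
                    matrix(hemi, nrow(asn), 100, byrow = TRUE)))
  expect_true(all(asn >= 1 & asn <= 100))

  # spun maps keep their within-hemisphere spatial autocorrelation
  maps <- drawSAMaps(200, seed = 5)
  orig <- vapply(1:200, function(i) moranWithinHemisphere(maps[i, ], geom),
                 numeric(1))
  spun <- vapply(1:200, function(i) {
    moranWithinHemisphere(maps[i, asn[i, ]], geom)
  }, numeric(1))
  expect_lt(abs(mean(spun) - mean(orig)) / abs(mean(orig)), 0.10)

  expect_error(buildSpinEnsemble(geom, 0), "nPerm")
})

test_that("spin ensembles regenerate identically from the same seed", {
  geom <- geom60()
  a <- buildSpinEnsemble(geom, 20, seed = 9)
  b <- buildSpinEnsemble(geom, 20, seed = 9)
  expect_identical(assignments(a), assignments(b))
})

test_that("permutation p-values follow the (1+k)/(1+N) convention", {
  nulls <- seq_len(9999) / 10000
  expect_equal(spinPvalue(2, nulls, "one_greater"), 1 / 10000)
  expect_equal(spinPvalue(0.5, rep(0.5, 99), "one_greater"), 1)
  expect_equal(spinPvalue(0.5, rep(0.5, 99), "two"), 1)
  expect_gte(spinPvalue(Inf, stats::rnorm(100), "one_greater"), 1 / 101)
  expect_error(spinPvalue(1, c(0.2, NaN)), "finite")
  expect_error(spinPvalue(1, numeric(0)), "finite")
})

test_that("spin p-values are calibrated under independent SA maps", {
  spins <- spins300()
  asn <- assignments(spins)
  x <- drawSAMaps(200, seed = 31)
  y <- drawSAMaps(200, seed = 32)
  ps <- vapply(1:200, function(i) {
    xs <- matrix(x[i, t(asn)], 100, nrow(asn))
    spinPvalue(stats::cor(x[i, ], y[i, ]),
               as.vector(stats::cor(xs, y[i, ])), "two")
  }, numeric(1))
  # type-I error at alpha = .05 within a generous binomial window
  expect_gt(mean(ps <= 0.05), 0.01)
  expect_lt(mean(ps <= 0.05), 0.11)
})

test_that("length-binned rewiring preserves degrees on a ring lattice", {
  # ring: every edge has the same length, one bin
  n <- 16
  geomIds <- sprintf("p%02d", 1:n)
  angle <- 2 * pi * (0:(n - 1)) / n
  cent <- cbind(cos(angle), sin(angle), 0) * 50
  sph <- cbind(cos(angle), sin(angle), 0)
  rownames(cent) <- rownames(sph) <- geomIds
  geom <- new("ParcelGeometry", regionIds = geomIds, centroids = cent,
              sphereCoords = sph,
              hemisphere = rep(c("left", "right"), each = n / 2),
              medialWall = matrix(numeric(0), 0, 3),
              distance = as.matrix(stats::dist(cent)))
  sc <- matrix(0, n, n)
  for (i in 1:n) {
    j <- i %% n + 1
    sc[i, j] <- sc[j, i] <- stats::runif(1, 0.5, 1)
  }
  ens <- rewirePreservingLength(sc, geom, nBins = 1, nNulls = 10, seed = 3)
  for (m in nullMatrices(ens)) {
    expect_equal(unname(rowSums(m > 0)), rep(2, n))
    expect_equal(sum(m > 0), sum(sc > 0))
    expect_equal(sort(m[m > 0]), sort(sc[sc > 0]))
  }
})

test_that("rewired nulls preserve per-bin edge counts exactly", {
  geom <- geom100()
  sim <- receptorSimilarity(atlas19()$atlas)
  sc <- generateConnectomes(geom, sim, density = 0.15, seed = 13)$sc
  ens <- rewirePreservingLength(sc, geom, nNulls = 10, seed = 4)
  d <- distanceMatrix(geom)
  binOf <- findInterval(d, ens@binEdges, left.open = TRUE)
  ref <- table(binOf[upper.tri(sc) & sc > 0])
  for (m in nullMatrices(ens)) {
    expect_identical(table(binOf[upper.tri(m) & m > 0]), ref)
    expect_equal(unname(rowSums(m > 0)), unname(rowSums(sc > 0)))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
})

test_that("connected contrast matches hand computation on a toy graph", {
  # 4 nodes, edges 1-2 and 3-4; similarity set by hand
  sc <- matrix(0, 4, 4)
  sc[1, 2] <- sc[2, 1] <- 1
  sc[3, 4] <- sc[4, 3] <- 1
  sim <- matrix(0, 4, 4)
  sim[upper.tri(sim)] <- c(0.9, 0.1, 0.2, 0.3, 0.4, 0.8)
  sim <- sim + t(sim)
  diag(sim) <- 1
  # connected pairs: (1,2) = 0.9 and (3,4) = 0.8; unconnected: 0.1/0.2/0.3/0.4
  expected <- mean(c(0.9, 0.8)) - mean(c(0.1, 0.2, 0.3, 0.4))
  ens <- new("RewiredEnsemble", matrices = list(sc), binEdges = c(-Inf, Inf),
             nSwaps = 0L, seed = 1L)
  res <- connectedContrastTest(sim, sc, ens)
  expect_equal(res$statistic, expected, tolerance = 1e-12)

  flat <- matrix(0.5, 4, 4)
  expect_equal(connectedContrastTest(flat, sc, ens)$statistic, 0)

  full <- matrix(1, 4, 4) - diag(4)
  expect_error(connectedContrastTest(sim, full, ens), "unconnected")
})

test_that("planted connected-edge similarity boost is detected", {
  geom <- geom100()
  sim <- receptorSimilarity(atlas19()$atlas)
  sc <- generateConnectomes(geom, sim, density = 0.2, seed = 14)$sc
  boosted <- sim
  boosted[sc > 0] <- boosted[sc > 0] + 0.3
  boosted <- (boosted + t(boosted)) / 2
  diag(boosted) <- 1
  ens <- rewirePreservingLength(sc, geom, nNulls = 200, seed = 15)
  res <- connectedContrastTest(boosted, sc, ens)
  expect_lte(res$p, 0.01)
})

test_that("label contrast detects planted modularity and handles nulls", {
  geom <- geom100()
  spins <- spins300()
  labels <- rep(c("A", "B", "C", "D"), each = 25)

  flat <- matrix(0.4, 100, 100)
  diag(flat) <- 1
  expect_equal(labelContrastTest(flat, labels, spins)$statistic, 0)

  # modular similarity aligned with the labels
  sim <- matrix(0.1, 100, 100)
  same <- outer(labels, labels, "==")
  sim[same] <- 0.6
  diag(sim) <- 1
  res <- labelContrastTest(sim, labels, spins)
  expect_lte(res$p, 0.01)
  expect_gt(res$statistic, 0.4)

  # plain-permutation fallback for incomplete-coverage data
  resPerm <- labelContrastTest(sim, labels, spins = NULL, nPerm = 200,
                               seed = 2)
  expect_lte(resPerm$p, 0.01)

  expect_error(labelContrastTest(sim, rep("A", 100), spins), "labels")
})

test_that("BH correction rejects and adjusts as expected", {
  single <- fdrCorrect(0.03, q = 0.05)
  expect_true(single$rejected)
  expect_equal(single$adjusted, 0.03)

  all4 <- fdrCorrect(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(all4$rejected))
  expect_equal(all4$adjusted, stats::p.adjust(c(0.01, 0.02, 0.03, 0.04),
                                              "BH"))
  expect_error(fdrCorrect(c(0.2, 1.4)), "0, 1")

  # FDR control under the global null: rejection proportion ~ alpha * V/m
  set.seed(41)
  falseRej <- replicate(500, {
    mean(fdrCorrect(stats::runif(20), q = 0.05)$rejected)
  })
  expect_lte(mean(falseRej), 0.05 + 0.02)
})
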
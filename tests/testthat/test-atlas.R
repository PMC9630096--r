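test_that("tracer map combination is a weighted average of z-scored maps", {
  m1 <- c(2, 4, 9, 1, 6)
  m2 <- c(1, 3, 8, 2, 7)
  # direct arithmetic oracle
  z1 <- (m1 - mean(m1)) / stats::sd(m1)
  z2 <- (m2 - mean(m2)) / stats::sd(m2)
  avg <- (1 * z1 + 3 * z2) / 4
  expected <- (avg - mean(avg)) / stats::sd(avg)
  expect_equal(unname(combineTracerMaps(list(m1, m2), weights = c(1, 3))),
               expected, tolerance = 1e-12)

  # identical maps: combination is the common z-scored map
  expect_equal(unname(combineTracerMaps(list(m1, m1), weights = c(2, 5))),
               z1, tolerance = 1e-12)

  # perfectly anticorrelated z-scored maps cancel to a zero-variance vector
  expect_warning(
    expect_error(combineTracerMaps(list(c(1, 2, 3), c(3, 2, 1)),
                                   weights = c(1, 1)),
                 "zero-variance"),
    "correlate below")
  expect_error(combineTracerMaps(list(c(1, 2), c(1, 2, 3)), c(1, 1)),
               "length")
})

test_that("atlas assembly z-scores columns and validates regions", {
  geom <- geom100()
  raw <- matrix(stats::rnorm(100 * 19, mean = 5, sd = 3), 100, 19,
                dimnames = list(regionIds(geom), sprintf("R%02d", 1:19)))
  meta <- data.frame(receptor = colnames(raw), row.names = colnames(raw))
  atlas <- assembleAtlas(raw, meta)
  x <- densities(atlas)
  expect_equal(dim(x), c(100L, 19L))
  expect_true(all(abs(colMeans(x)) < 1e-9))
  expect_true(all(abs(apply(x, 2, stats::sd) - 1) < 1e-9))

  bad <- raw
  bad[, 4] <- 2
  expect_error(assembleAtlas(bad, meta), "zero-variance")

  maps <- list(a = c(L1 = 1, L2 = 2, L3 = 5, L4 = 3),
               b = c(L1 = 2, L2 = 1, L4 = 9))  # L3 missing
  expect_error(assembleAtlas(maps, data.frame(row.names = c("a", "b"))),
               "L3")
})

test_that("receptor similarity matches pairwise fingerprint correlation", {
  set.seed(17)
  base <- matrix(stats::rnorm(4 * 5), 4, 5)
  base[2, ] <- base[1, ]            # duplicate fingerprint
  # antisymmetric block keeps column means exactly zero, so duplication and
  # negation both survive the per-column z-scoring
  x <- rbind(base, -base)
  dimnames(x) <- list(paste0("r", 1:8), paste0("R0", 1:5))
  atlas <- assembleAtlas(x, data.frame(row.names = colnames(x)))
  dens <- densities(atlas)
  sim <- receptorSimilarity(atlas)
  expect_equal(sim, (sim + t(sim)) / 2)
  expect_equal(unname(diag(sim)), rep(1, 8))
  expect_equal(sim[1, 2], 1, tolerance = 1e-12)
  expect_equal(sim[1, 5], -1, tolerance = 1e-12)   # fingerprint of -r1
  expect_true(all(sim >= -1 - 1e-12 & sim <= 1 + 1e-12))
  expect_equal(unname(sim[lower.tri(sim)]),
               unname(stats::cor(t(dens))[lower.tri(sim)]),
               tolerance = 1e-12)

  # permutation equivariance: sim(P X) = P sim(X) P'
  perm <- sample(8)
  permAtlas <- chemoarch:::.newAtlas(dens[perm, ],
                                     data.frame(row.names = colnames(x)))
  expect_equal(receptorSimilarity(permAtlas), sim[perm, perm],
               tolerance = 1e-12)
})

test_that("similarity is invariant to per-receptor affine rescaling", {
  set.seed(21)
  raw <- matrix(stats::rnorm(30 * 6), 30, 6)
  meta <- data.frame(row.names = paste0("R", 1:6))
  colnames(raw) <- rownames(meta)
  rescaled <- sweep(sweep(raw, 2, c(2, 3, 0.5, 10, 1, 7), "*"),
                    2, c(-5, 0, 3, 1, 2, 0), "+")
  expect_equal(receptorSimilarity(assembleAtlas(raw, meta)),
               receptorSimilarity(assembleAtlas(rescaled, meta)),
               tolerance = 1e-10)
})

test_that("distance decay fit recovers planted parameters", {
  geom <- geom100()
  d <- distanceMatrix(geom)
  sim <- 0.8 * exp(-d / 20)
  diag(sim) <- 1
  fit <- fitDistanceDecay(sim, geom)
  expect_equal(fit@amplitude, 0.8, tolerance = 1e-6)
  expect_equal(fit@rate, 0.05, tolerance = 1e-6)
  expect_equal(fit@offset, 0, tolerance = 1e-6)

  flat <- matrix(0.3, 100, 100)
  flatFit <- fitDistanceDecay(flat, geom)
  expect_equal(flatFit@rate, 0)
  expect_equal(flatFit@amplitude + flatFit@offset, 0.3, tolerance = 1e-9)

  rates <- vapply(1:20, function(s) {
    set.seed(s)
    e <- matrix(stats::rnorm(100 * 100, sd = 0.05), 100, 100)
    noisy <- sim + (e + t(e)) / sqrt(2)
    diag(noisy) <- 1
    fitDistanceDecay(noisy, geom)@rate
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05) / 0.05, 0.10)
})

test_that("principal gradient has fixed sign and valid variance fractions", {
  geom <- geom100()
  rank1 <- generateReceptorAtlas(geom, 6, nLatent = 1, noiseSd = 0, seed = 3)
  pg <- principalGradient(rank1$atlas)
  expect_equal(pg$varExplained[1], 1, tolerance = 1e-12)
  expect_equal(abs(stats::cor(pg$gradient, rank1$truth$latents[, 1])), 1,
               tolerance = 1e-10)

  pg19 <- principalGradient(atlas19()$atlas)
  expect_equal(sum(pg19$varExplained), 1, tolerance = 1e-9)
  expect_true(all(diff(pg19$varExplained) <= 1e-12))
  expect_lt(abs(mean(pg19$gradient)), 1e-9)
  expect_gt(sum(pg19$loadings), 0)
})

test_that("class ANOVA matches the standard linear-model F test", {
  set.seed(31)
  map <- stats::rnorm(24)
  labels <- rep(c("idiotypic", "unimodal", "heteromodal", "paralimbic"), 6)
  res <- classAnova(map, labels)
  oracle <- stats::anova(stats::lm(map ~ factor(labels)))
  expect_equal(res$statistic, oracle$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, oracle$`Pr(>F)`[1], tolerance = 1e-12)
  expect_false(res$overflow)

  # equal class means: F is exactly zero
  flat <- classAnova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)

  # zero within-class variance: infinite F flagged, not an error
  ovf <- classAnova(c(0, 0, 0, 1, 1, 1), rep(c("a", "b"), each = 3))
  expect_true(ovf$overflow)
  expect_identical(ovf$statistic, Inf)

  expect_error(classAnova(1:5, c("a", "a", "b", "b", "c")), "singleton")
})

test_that("age regression matches a per-region lm oracle", {
  atlas <- atlas19()$atlas
  out <- regressAge(atlas)
  x <- densities(atlas)
  age <- receptorMeta(atlas)$meanAge
  oracle <- t(apply(x, 1, function(row) stats::resid(stats::lm(row ~ age))))
  oracle <- apply(oracle, 2, function(col) (col - mean(col)) / stats::sd(col))
  expect_equal(unname(densities(out)), unname(oracle), tolerance = 1e-9)
  # pre-re-z-scoring residuals are orthogonal to age in every region
  resid <- t(apply(x, 1, function(row) stats::resid(stats::lm(row ~ age))))
  orth <- apply(resid, 1, function(r) abs(stats::cor(r, age)))
  expect_lt(max(orth), 1e-10)

  meta <- receptorMeta(atlas)
  meta$meanAge <- 50
  flatAge <- chemoarch:::.newAtlas(x, meta)
  expect_error(regressAge(flatAge), "distinct")
})

test_that("no single receptor dominates the similarity structure", {
  loo <- looSimilarityRobustness(atlas19()$atlas)
  expect_length(loo, 19)
  expect_named(loo, sprintf("R%02d", 1:19))
  expect_true(all(loo > 0.9))
})
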
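#' Generate a stylized two-hemisphere cortical parcellation
#'
#' Places `nRegions/2` parcels per hemisphere quasi-uniformly on a unit
#' sphere via a Fibonacci lattice and applies one seed-derived random
#' rotation (mirrored across hemispheres; the right-hemisphere sphere is
#' the x-mirror image of the left). Euclidean centroids put each hemisphere
#' on a sphere of radius `radius/2` mm centered at -/+ `radius/2` on the x
#' axis, so the two spheres touch at the midline and the whole brain spans
#' `2 * radius` mm at most. The medial-wall marker of each hemisphere is
#' the sphere pole facing the midline.
#'
#' The geometry makes no attempt to mimic cortical folding or laminar
#' structure; it is a stylized sphere pair whose only purpose is to carry
#' realistic pairwise distances and a spherical projection for spin tests.
#'
#' @param nRegions even integer >= 4; split equally across hemispheres.
#' @param seed integer seed; the same seed reproduces the geometry exactly.
#' @param radius sphere radius in mm (default 70, hemisphere span ~140 mm).
#' @return A [ParcelGeometry-class].
#' @examples
#' geom <- generateParcellation(20, seed = 1)
#' table(hemispheres(geom))
#' @export
generateParcellation <- function(nRegions, seed, radius = 70) {
  if (length(nRegions) != 1 || nRegions < 4 || nRegions %% 2 != 0) {
    stop("nRegions must be an even integer >= 4", call. = FALSE)
  }
  nh <- nRegions / 2
  lat <- .fibonacciSphere(nh)
  rot <- .withSeed(seed, .randomRotation())
  left <- lat %*% t(rot)
  mirror <- diag(c(-1, 1, 1))
  right <- left %*% mirror    # x-negated mirror image

  sphere <- rbind(left, right)
  hemi <- rep(c("left", "right"), each = nh)

  # Each hemisphere is a full sphere of radius 0.4 * radius centered at
  # -/+ 0.6 * radius on the x axis (overall half-span `radius`, inter-
  # hemispheric gap 0.4 * radius). Within a hemisphere the centroid
  # distance is exactly proportional to the chordal sphere distance, so
  # spherical rotations preserve the within-hemisphere distance structure
  # the spin null model relies on; the gap keeps cross-hemisphere
  # covariance (which hemisphere-separate spins cannot preserve) modest.
  rh <- 0.4 * radius
  cx <- 0.6 * radius
  cent <- sphere * rh
  cent[seq_len(nh), 1] <- cent[seq_len(nh), 1] - cx
  cent[nh + seq_len(nh), 1] <- cent[nh + seq_len(nh), 1] + cx

  ids <- c(sprintf("L%03d", seq_len(nh)), sprintf("R%03d", seq_len(nh)))
  rownames(cent) <- rownames(sphere) <- ids

  # Medial wall: the pole of each hemisphere sphere facing the midline.
  mw <- rbind(left = c(1, 0, 0), right = c(-1, 0, 0))

  new("ParcelGeometry",
      regionIds = ids, centroids = cent, sphereCoords = sphere,
      hemisphere = hemi, medialWall = mw,
      distance = as.matrix(stats::dist(cent)))
}

# Fibonacci lattice of n points on the unit sphere.
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Upper Cholesky factor of the exponential-covariance matrix
# sigma^2 exp(-d / lengthScale), diagonal-jittered to positive definiteness.
.saMapFactor <- function(geometry, lengthScale, sigma) {
  stopifnot(is(geometry, "ParcelGeometry"))
  if (lengthScale <= 0) stop("lengthScale must be > 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  d <- distanceMatrix(geometry)
  cv <- sigma^2 * exp(-d / lengthScale)
  cv <- (cv + t(cv)) / 2
  n <- nrow(cv)
  diag(cv) <- diag(cv) + 1e-10 * sum(diag(cv)) / n
  u <- tryCatch(chol(cv), error = function(e) {
    stop("covariance not positive definite after jitter: ",
         conditionMessage(e), call. = FALSE)
  })
  u
}

#' Sample spatially autocorrelated regional maps
#'
#' Draws from a zero-mean Gaussian field over parcels with covariance
#' `sigma^2 * exp(-distance / lengthScale)` (distances in mm). The
#' covariance matrix is symmetrized and its diagonal jittered by
#' `1e-10 * trace / n` before Cholesky factorization.
#'
#' @param geometry a [ParcelGeometry-class].
#' @param lengthScale covariance length scale, mm (> 0).
#' @param sigma field amplitude (>= 0); `0` yields all-zero maps.
#' @param seed integer seed.
#' @param nDraws number of independent maps to draw.
#' @return A numeric vector (one draw) or an `nDraws` x regions matrix.
#' @export
sampleSAMap <- function(geometry, lengthScale = 20, sigma = 1, seed = 1,
                        nDraws = 1) {
  n <- length(regionIds(geometry))
  if (sigma == 0) {
    out <- matrix(0, nDraws, n)
  } else {
    u <- .saMapFactor(geometry, lengthScale, sigma)
    z <- .withSeed(seed, matrix(stats::rnorm(nDraws * n), nDraws, n))
    out <- z %*% u
  }
  colnames(out) <- regionIds(geometry)
  if (nDraws == 1) out[1, ] else out
}

#' Generate a receptor atlas with a planted low-rank gradient
#'
#' Each receptor map is a random linear mixture of `nLatent` spatially
#' autocorrelated latent maps plus independent Gaussian noise, then z-scored
#' across regions. The planted gradient recorded in the ground truth is the
#' first principal component of the noiseless mixture (the latent map itself
#' when `nLatent = 1`). Synthetic study metadata (participant counts, mean
#' ages, class annotations) are attached so metadata-dependent operations
#' are exercisable.
#'
#' @param geometry a [ParcelGeometry-class].
#' @param nReceptors number of receptor/transporter maps.
#' @param nLatent number of latent spatial components (1..nReceptors).
#' @param noiseSd standard deviation of the independent noise (>= 0).
#' @param lengthScale latent-map covariance length scale, mm.
#' @param seed integer seed.
#' @return A list with elements `atlas` (a [ReceptorAtlas-class]) and
#'   `truth` (latent maps, mixing weights, planted gradient, parameters).
#' @export
generateReceptorAtlas <- function(geometry, nReceptors = 19, nLatent = 3,
                                  noiseSd = 0.2, lengthScale = 20, seed = 1) {
  if (nLatent < 1 || nLatent > nReceptors) {
    stop("nLatent must lie in [1, nReceptors]", call. = FALSE)
  }
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  n <- length(regionIds(geometry))
  seeds <- .subSeeds(seed, 3)
  latents <- sampleSAMap(geometry, lengthScale, sigma = 1, seed = seeds[1],
                         nDraws = nLatent)
  if (nLatent == 1) latents <- matrix(latents, 1, n)
  latents <- t(latents)                       # regions x nLatent

  gen <- .withSeed(seeds[2], {
    # Mixing weights are orthonormal rows of a random orthogonal matrix,
    # scaled so each receptor's signal variance is ~1. This confines
    # receptor-receptor correlation to the shared latent span instead of
    # adding artificial collinearity through the mixing itself (dense
    # Gaussian mixing makes planted predictors unidentifiable).
    o <- qr.Q(qr(matrix(stats::rnorm(nReceptors^2), nReceptors, nReceptors)))
    w <- o[seq_len(nLatent), , drop = FALSE] * sqrt(nReceptors / nLatent)
    noise <- matrix(stats::rnorm(n * nReceptors, sd = noiseSd), n, nReceptors)
    list(w = w, noise = noise)
  })
  signal <- latents %*% gen$w
  dens <- .zscoreCols(signal + gen$noise)
  rNames <- sprintf("R%02d", seq_len(nReceptors))
  colnames(dens) <- rNames
  rownames(dens) <- regionIds(geometry)

  meta <- .withSeed(seeds[3], data.frame(
    receptor = rNames,
    studyN = sample(5:200, nReceptors, replace = TRUE),
    meanAge = round(stats::runif(nReceptors, 20, 70), 1),
    excitatory = sample(c(TRUE, FALSE), nReceptors, replace = TRUE),
    ionotropic = sample(c(TRUE, FALSE), nReceptors, replace = TRUE),
    monoamine = sample(c(TRUE, FALSE), nReceptors, replace = TRUE),
    gProtein = sample(c("Gs", "Gi", "Gq"), nReceptors, replace = TRUE),
    row.names = rNames
  ))
  meta$gProtein[meta$ionotropic] <- NA_character_

  atlas <- .newAtlas(dens, meta)
  gradSignal <- .zscoreCols(signal)
  sv <- svd(gradSignal)
  gradient <- sv$u[, 1] * sv$d[1]
  if (sum(sv$v[, 1]) < 0) gradient <- -gradient

  list(
    atlas = atlas,
    truth = list(
      latents = latents, weights = gen$w, gradient = gradient,
      noiseSd = noiseSd, decayRate = 1 / lengthScale, seed = seed
    )
  )
}

# Internal ReceptorAtlas constructor from a regions x receptors matrix.
.newAtlas <- function(densities, meta) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(density = t(densities)),
    rowData = S4Vectors::DataFrame(meta)
  )
  new("ReceptorAtlas", se)
}

#' Generate paired structural and functional connectomes
#'
#' The structural connectome (SC) draws undirected edges without replacement
#' with probability decreasing exponentially in centroid distance until the
#' target density is reached; edge weights are uniform on (0.1, 1]. The
#' functional connectome (FC) is built as the z-scored communicability of
#' the SC plus `couplingBeta` times the supplied receptor similarity matrix
#' plus symmetric Gaussian noise — so receptor augmentation of
#' structure-function coupling has a planted, recoverable effect size.
#'
#' @param geometry a [ParcelGeometry-class].
#' @param receptorSim symmetric region x region receptor similarity matrix.
#' @param density fraction of undirected edges present, in (0, 1).
#' @param couplingBeta planted receptor-similarity contribution to FC.
#' @param noiseSd sd of the symmetric FC noise.
#' @param decayScale SC connection-probability length scale, mm.
#' @param seed integer seed.
#' @return A list with `sc`, `fc` (matrices, symmetric, zero diagonal) and
#'   `truth` (planted parameters). A disconnected SC triggers a warning,
#'   not an error.
#' @export
generateConnectomes <- function(geometry, receptorSim, density = 0.2,
                                couplingBeta = 0, noiseSd = 0.1,
                                decayScale = 30, seed = 1) {
  if (density <= 0 || density >= 1) stop("density must lie in (0, 1)",
                                         call. = FALSE)
  .checkSquareSymmetric(receptorSim, "receptorSim")
  n <- length(regionIds(geometry))
  if (nrow(receptorSim) != n) {
    stop("receptorSim must match the geometry", call. = FALSE)
  }
  d <- distanceMatrix(geometry)
  ut <- which(upper.tri(d))
  m <- round(density * length(ut))
  seeds <- .subSeeds(seed, 2)

  sc <- matrix(0, n, n)
  .withSeed(seeds[1], {
    prob <- exp(-d[ut] / decayScale)
    keep <- sample(seq_along(ut), m, prob = prob)
    sc[ut[keep]] <- stats::runif(m, 0.1, 1)
  })
  sc <- sc + t(sc)
  dimnames(sc) <- list(regionIds(geometry), regionIds(geometry))
  if (!.isConnected(sc)) {
    warning("generated structural connectome is disconnected", call. = FALSE)
  }

  comm <- communicability(sc)
  cz <- comm
  v <- .upperTri(comm)
  cz[] <- (comm - mean(v)) / stats::sd(v)
  fc <- cz + couplingBeta * receptorSim
  noise <- .withSeed(seeds[2], matrix(stats::rnorm(n * n, sd = noiseSd), n, n))
  fc <- fc + (noise + t(noise)) / sqrt(2)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 0
  dimnames(fc) <- dimnames(sc)

  list(sc = sc, fc = fc,
       truth = list(couplingBeta = couplingBeta, noiseSd = noiseSd,
                    density = density, decayScale = decayScale, seed = seed))
}

# Connectivity check via breadth-first search on the binary adjacency.
.isConnected <- function(a) {
  n <- nrow(a)
  if (n == 0) return(TRUE)
  adj <- a > 0
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Generate target maps as noisy mixtures of receptor maps
#'
#' Each map is a weighted sum of the columns of the atlas named in
#' `activeSet` plus Gaussian noise scaled so that the signal-to-noise
#' variance ratio equals `snr`. Weight magnitudes are uniform on
#' (0.5, 1.5) with random sign, recorded in the ground truth.
#'
#' @param atlas a [ReceptorAtlas-class].
#' @param activeSet non-empty character or integer subset of receptors.
#' @param snr signal-variance / noise-variance ratio (> 0; `Inf` = no noise).
#' @param nMaps number of maps to generate.
#' @param seed integer seed.
#' @return A list with `maps` (regions x nMaps matrix) and `truth`
#'   (full-length weight matrix with zeros off the active set, `snr`).
#' @export
generateTargetMaps <- function(atlas, activeSet, snr = 10, nMaps = 1,
                               seed = 1) {
  x <- densities(atlas)
  if (length(activeSet) == 0) stop("activeSet must be non-empty",
                                   call. = FALSE)
  if (is.character(activeSet)) {
    missing <- setdiff(activeSet, colnames(x))
    if (length(missing)) stop("unknown receptors: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    active <- match(activeSet, colnames(x))
  } else {
    active <- as.integer(activeSet)
  }
  if (!(snr > 0)) stop("snr must be > 0", call. = FALSE)
  n <- nrow(x)
  maps <- matrix(0, n, nMaps)
  wFull <- matrix(0, ncol(x), nMaps,
                  dimnames = list(colnames(x), paste0("map", seq_len(nMaps))))
  .withSeed(seed, {
    for (k in seq_len(nMaps)) {
      w <- stats::runif(length(active), 0.5, 1.5) *
        sample(c(-1, 1), length(active), replace = TRUE)
      signal <- x[, active, drop = FALSE] %*% w
      noiseVar <- if (is.finite(snr)) stats::var(as.vector(signal)) / snr else 0
      maps[, k] <- signal + stats::rnorm(n, sd = sqrt(noiseVar))
      wFull[active, k] <- w
    }
  })
  rownames(maps) <- rownames(x)
  colnames(maps) <- colnames(wFull)
  list(maps = maps,
       truth = list(weights = wFull, activeSet = colnames(x)[active],
                    snr = snr, seed = seed))
}

#' Generate a regional feature matrix sharing a latent component
#'
#' Builds a region x term matrix ("cognitive" block) whose every column is
#' `latentCorr` times the atlas's principal receptor gradient plus
#' `sqrt(1 - latentCorr^2)` times an independent spatially autocorrelated
#' noise map, z-scored per term. At `latentCorr = 1` the cross-covariance
#' with the atlas is exactly rank one; at `0` the two blocks are
#' independent.
#'
#' @param atlas a [ReceptorAtlas-class].
#' @param geometry the [ParcelGeometry-class] the atlas lives on.
#' @param nTerms number of term columns.
#' @param latentCorr planted shared-component strength in \[0, 1\].
#' @param lengthScale noise-map covariance length scale, mm.
#' @param seed integer seed.
#' @return A list with `terms` (regions x nTerms, z-scored columns) and
#'   `truth` (the shared latent map and `latentCorr`).
#' @export
generatePairedMatrix <- function(atlas, geometry, nTerms = 20,
                                 latentCorr = 0.5, lengthScale = 20,
                                 seed = 1) {
  if (latentCorr < 0 || latentCorr > 1) {
    stop("latentCorr must lie in [0, 1]", call. = FALSE)
  }
  g <- .zscore(principalGradient(atlas)$gradient, "principal gradient")
  n <- length(g)
  noise <- sampleSAMap(geometry, lengthScale, sigma = 1, seed = seed,
                       nDraws = nTerms)
  if (nTerms == 1) noise <- matrix(noise, 1, n)
  noise <- apply(noise, 1, .zscore)            # regions x nTerms
  terms <- latentCorr * matrix(g, n, nTerms) +
    sqrt(1 - latentCorr^2) * noise
  terms <- .zscoreCols(terms)
  dimnames(terms) <- list(regionIds(geometry),
                          sprintf("term%03d", seq_len(nTerms)))
  list(terms = terms,
       truth = list(latent = g, latentCorr = latentCorr, seed = seed))
}
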
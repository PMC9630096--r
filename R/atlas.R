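#' Combine tracer maps of the same receptor
#'
#' When several studies image the same receptor/transporter with the same
#' tracer, their group-average maps are merged: each map is z-scored across
#' regions, averaged with weights proportional to study participant counts,
#' and the result is re-z-scored. Absolute binding values from different
#' studies are not commensurate, which is why averaging happens on the
#' z-scored maps. Maps that correlate below `corThreshold` after z-scoring
#' trigger a warning (they may not measure the same spatial pattern).
#'
#' @param maps list of >= 2 numeric region vectors of equal length.
#' @param weights positive per-map weights (typically study n).
#' @param corThreshold pairwise Pearson r below which to warn (default 0.5).
#' @return The combined, z-scored region vector.
#' @export
combineTracerMaps <- function(maps, weights, corThreshold = 0.5) {
  if (!is.list(maps) || length(maps) < 2) {
    stop("need at least two maps to combine", call. = FALSE)
  }
  lens <- vapply(maps, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("maps must all have the same length", call. = FALSE)
  }
  if (length(weights) != length(maps) || any(weights <= 0)) {
    stop("weights must be positive, one per map", call. = FALSE)
  }
  z <- lapply(seq_along(maps), function(i) {
    .zscore(maps[[i]], label = paste0("map ", i))
  })
  zm <- do.call(cbind, z)
  cc <- stats::cor(zm)
  if (min(cc[upper.tri(cc)]) < corThreshold) {
    warning("some input maps correlate below ", corThreshold,
            " after z-scoring", call. = FALSE)
  }
  combined <- as.vector(zm %*% (weights / sum(weights)))
  out <- .zscore(combined, "combined map")
  names(out) <- names(maps[[1]])
  out
}

#' Assemble a receptor atlas from per-tracer region vectors
#'
#' Z-scores each receptor map across regions (sample sd) and stacks them
#' into a [ReceptorAtlas-class]. Vectors must agree on region identity: if
#' named, every map must cover exactly the same regions (reordered to the
#' first map's order); a missing region raises an error naming it.
#'
#' @param tracerTables named list of region vectors (one per receptor), or a
#'   regions x receptors numeric matrix with dimnames.
#' @param meta data.frame of per-receptor metadata with rows matching the
#'   receptor names; should carry `studyN`, `meanAge` and class columns.
#' @return A [ReceptorAtlas-class] (regions x receptors via [densities()]).
#' @export
assembleAtlas <- function(tracerTables, meta) {
  if (is.matrix(tracerTables)) {
    mats <- tracerTables
  } else {
    if (is.null(names(tracerTables))) {
      names(tracerTables) <- sprintf("R%02d", seq_along(tracerTables))
    }
    ref <- names(tracerTables[[1]])
    mats <- vapply(names(tracerTables), function(nm) {
      v <- tracerTables[[nm]]
      if (!is.null(ref) && !is.null(names(v))) {
        missing <- setdiff(ref, names(v))
        if (length(missing)) {
          stop("receptor ", nm, " is missing region ", missing[1],
               call. = FALSE)
        }
        v <- v[ref]
      } else if (length(v) != length(tracerTables[[1]])) {
        stop("receptor ", nm, " has a different number of regions",
             call. = FALSE)
      }
      v
    }, numeric(length(tracerTables[[1]])))
    rownames(mats) <- ref
  }
  dens <- .zscoreCols(mats)
  if (is.null(colnames(dens))) {
    colnames(dens) <- sprintf("R%02d", seq_len(ncol(dens)))
  }
  if (!all(rownames(meta) == colnames(dens)) &&
      !is.null(meta$receptor) && all(meta$receptor %in% colnames(dens))) {
    rownames(meta) <- meta$receptor
    meta <- meta[colnames(dens), , drop = FALSE]
  }
  if (nrow(meta) != ncol(dens)) {
    stop("metadata must have one row per receptor", call. = FALSE)
  }
  .newAtlas(dens, meta)
}

#' Receptor similarity matrix
#'
#' Pearson correlation between the receptor fingerprints (density vectors
#' across all receptors) of every pair of regions; the region x region
#' matrix is symmetric with unit diagonal. A region whose fingerprint has
#' zero variance is an error naming the region.
#'
#' @param atlas a [ReceptorAtlas-class] with >= `minReceptors` receptors.
#' @param minReceptors minimum fingerprint length for a meaningful Pearson
#'   correlation (default 3).
#' @return Symmetric numeric matrix in \[-1, 1\] with unit diagonal.
#' @export
receptorSimilarity <- function(atlas, minReceptors = 3) {
  x <- densities(atlas)
  if (ncol(x) < minReceptors) {
    stop("need at least ", minReceptors, " receptors", call. = FALSE)
  }
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance receptor fingerprint in region ",
         rownames(x)[which(sds == 0)[1]], call. = FALSE)
  }
  sim <- stats::cor(t(x))
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  sim
}

#' Fit the exponential distance decay of similarity
#'
#' Nonlinear least-squares fit of `sim = a * exp(-b * d) + c` over the
#' upper-triangle region pairs, with `b` constrained non-negative.
#' Initialization comes from a log-linear regression of
#' `log(sim - min(sim) + eps)` on distance. A constant similarity matrix is
#' returned as the degenerate flat fit (`b = 0`, `a + c` equal to the
#' constant) rather than an error.
#'
#' @param similarity symmetric region x region similarity matrix.
#' @param geometry matching [ParcelGeometry-class].
#' @return A [DecayFit-class].
#' @export
fitDistanceDecay <- function(similarity, geometry) {
  .checkSquareSymmetric(similarity, "similarity")
  d <- .upperTri(distanceMatrix(geometry))
  s <- .upperTri(similarity)
  if (any(d <= 0)) stop("pairwise distances must be positive", call. = FALSE)
  if (stats::sd(s) < 1e-12) {
    return(new("DecayFit", amplitude = 0, rate = 0, offset = mean(s),
               rss = sum((s - mean(s))^2), nPairs = length(s)))
  }
  eps <- 1e-6
  shifted <- s - min(s) + eps
  init <- stats::lm(log(shifted) ~ d)
  a0 <- unname(exp(stats::coef(init)[1]))
  b0 <- unname(max(1e-6, -stats::coef(init)[2]))
  c0 <- min(s)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ a * exp(-b * d) + c,
                      start = list(a = a0, b = b0, c = c0),
                      lower = c(a = -Inf, b = 0, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    cond <- simpleError(paste0("distance-decay fit did not converge: ",
                               conditionMessage(fit)))
    cond$initialGuess <- c(a = unname(a0), b = unname(b0), c = unname(c0))
    stop(cond)
  }
  cf <- stats::coef(fit)
  new("DecayFit", amplitude = unname(cf["a"]), rate = unname(cf["b"]),
      offset = unname(cf["c"]), rss = sum(stats::resid(fit)^2),
      nPairs = length(s))
}

#' Principal receptor gradient
#'
#' First principal component of the z-scored region x receptor matrix: a
#' regional score summarizing the dominant axis of receptor co-variation.
#' The sign is fixed so that the sum of the PC1 receptor loadings is
#' positive; variance-explained fractions over all components sum to 1.
#'
#' @param atlas a [ReceptorAtlas-class].
#' @return A list with `gradient` (region scores), `varExplained`
#'   (non-increasing fractions summing to 1) and `loadings` (PC1 receptor
#'   loadings).
#' @export
principalGradient <- function(atlas) {
  x <- densities(atlas)
  sv <- svd(x)
  if (sv$d[1] < 1e-12) stop("atlas matrix has rank 0", call. = FALSE)
  varExplained <- sv$d^2 / sum(sv$d^2)
  sgn <- if (sum(sv$v[, 1]) < 0) -1 else 1
  gradient <- sgn * sv$u[, 1] * sv$d[1]
  names(gradient) <- rownames(x)
  loadings <- sgn * sv$v[, 1]
  names(loadings) <- colnames(x)
  list(gradient = gradient, varExplained = varExplained, loadings = loadings)
}

#' One-way ANOVA of a regional map across classes
#'
#' Standard one-way ANOVA F statistic of the map over region classes (e.g.
#' laminar differentiation levels or intrinsic networks). Zero within-class
#' variance with distinct class means yields an infinite F, reported with an
#' `overflow` flag instead of an error.
#'
#' @param map numeric region vector.
#' @param labels class label per region; >= 2 classes, each with >= 2
#'   regions.
#' @return A list with `statistic` (F), `p`, `df` (between, within) and
#'   `overflow` (logical).
#' @export
classAnova <- function(map, labels) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two classes", call. = FALSE)
  if (any(tab < 2)) {
    stop("singleton class: ", names(tab)[tab < 2][1], call. = FALSE)
  }
  groups <- split(map, labels)
  k <- length(groups)
  n <- length(map)
  grand <- mean(map)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1
  dfw <- n - k
  if (ssw < 1e-14 * max(1, ssb)) {
    return(list(statistic = Inf, p = 0, df = c(dfb, dfw), overflow = TRUE))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  list(statistic = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       df = c(dfb, dfw), overflow = FALSE)
}

#' Remove the study-age relationship from receptor densities
#'
#' PET studies differ in the mean age of their participants. For each
#' region separately, the receptor fingerprint (the z-scored densities
#' across receptors) is regressed on the per-receptor mean participant age,
#' and the residuals replace the densities; columns are then re-z-scored.
#' Residuals are exactly orthogonal to the age vector within each region
#' before the final re-z-scoring.
#'
#' @param atlas a [ReceptorAtlas-class] whose metadata carries `meanAge`.
#' @return An age-residualized [ReceptorAtlas-class].
#' @export
regressAge <- function(atlas) {
  x <- densities(atlas)
  meta <- receptorMeta(atlas)
  age <- meta$meanAge
  if (is.null(age) || anyNA(age)) {
    stop("meanAge must be present for every receptor", call. = FALSE)
  }
  if (length(unique(age)) < 3) {
    stop("need at least 3 distinct mean ages", call. = FALSE)
  }
  design <- cbind(1, age)
  # One QR serves every region: residuals of each fingerprint on age.
  qrd <- qr(design)
  resid <- t(qr.resid(qrd, t(x)))
  dens <- .zscoreCols(resid)
  dimnames(dens) <- dimnames(x)
  .newAtlas(dens, meta)
}

#' Leave-one-receptor-out similarity robustness
#'
#' Drops each receptor in turn, recomputes the receptor similarity matrix,
#' and correlates its upper triangle with the full-atlas similarity. Values
#' near 1 mean no single receptor dominates the similarity structure.
#'
#' @param atlas a [ReceptorAtlas-class] with >= 4 receptors.
#' @return Named numeric vector of Pearson correlations, one per receptor
#'   (NA with a warning if a reduced similarity is constant).
#' @export
looSimilarityRobustness <- function(atlas) {
  x <- densities(atlas)
  p <- ncol(x)
  if (p < 4) stop("need at least 4 receptors", call. = FALSE)
  full <- .upperTri(receptorSimilarity(atlas))
  meta <- receptorMeta(atlas)
  out <- vapply(seq_len(p), function(k) {
    sub <- .newAtlas(x[, -k, drop = FALSE], meta[-k, , drop = FALSE])
    s <- .upperTri(receptorSimilarity(sub, minReceptors = 3))
    if (stats::sd(s) < 1e-12 || stats::sd(full) < 1e-12) {
      warning("constant similarity when dropping receptor ", colnames(x)[k],
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(full, s)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}
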
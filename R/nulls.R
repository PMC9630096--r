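#' Build a spin-permutation ensemble
#'
#' For each repetition one rotation uniform on SO(3) is applied to the left
#' hemisphere's spherical parcel coordinates and its x-mirrored conjugate to
#' the right's, and every original parcel is reassigned the index of the
#' nearest rotated parcel of the same hemisphere (ties broken by lowest
#' index). If a hemisphere carries a medial-wall marker and the rotated
#' marker is the nearest point, the next most proximal rotated parcel is
#' used instead. Spun maps are obtained as `map[assignments(spins)[p, ]]`.
#'
#' @param geometry a [ParcelGeometry-class] with sphere coordinates and
#'   hemisphere labels.
#' @param nPerm number of rotations (>= 1).
#' @param seed integer seed.
#' @return A [SpinEnsemble-class].
#' @export
buildSpinEnsemble <- function(geometry, nPerm, seed = 1) {
  if (nPerm < 1) stop("nPerm must be >= 1", call. = FALSE)
  n <- length(regionIds(geometry))
  out <- matrix(NA_integer_, nPerm, n)
  .withSeed(seed, {
    for (p in seq_len(nPerm)) {
      out[p, ] <- .spinAssignment(geometry, .randomRotation())
    }
  })
  new("SpinEnsemble", assignments = out, seed = as.integer(seed),
      hemisphere = hemispheres(geometry))
}

# One assignment row for a given left-hemisphere rotation; the right
# hemisphere gets the x-flip conjugate M R M (M = diag(-1, 1, 1)) so the
# two hemispheres spin as mirror images.
.spinAssignment <- function(geometry, rotLeft) {
  mirror <- diag(c(-1, 1, 1))
  rots <- list(left = rotLeft, right = mirror %*% rotLeft %*% mirror)
  hemi <- hemispheres(geometry)
  coords <- sphereCoords(geometry)
  assignment <- integer(length(hemi))
  for (h in c("left", "right")) {
    idx <- which(hemi == h)
    ph <- coords[idx, , drop = FALSE]
    rotated <- ph %*% t(rots[[h]])
    # Unit vectors: nearest rotated point = largest cosine; which.max breaks
    # ties at the lowest index. The medial-wall marker carries no parcel
    # value, so "assign the next most proximal parcel when the marker is
    # nearest" reduces to taking the nearest rotated *parcel* — the marker
    # is simply never a candidate source.
    cosSim <- ph %*% t(rotated)
    pick <- apply(cosSim, 1, which.max)
    assignment[idx] <- idx[pick]
  }
  assignment
}

#' Permutation p-value with the (1 + k) / (1 + N) convention
#'
#' `p = (1 + #null as or more extreme) / (1 + nPerm)`; the minimum
#' attainable p is `1 / (nPerm + 1)`, never 0. The two-tailed version
#' compares absolute deviations from the null mean.
#'
#' @param observed scalar observed statistic.
#' @param nullStats numeric vector of null statistics (finite, non-empty).
#' @param tail `"one_greater"`, `"one_less"` or `"two"`.
#' @return The permutation p-value.
#' @export
spinPvalue <- function(observed, nullStats,
                       tail = c("one_greater", "one_less", "two")) {
  tail <- match.arg(tail)
  if (length(nullStats) == 0 || any(!is.finite(nullStats))) {
    stop("nullStats must be non-empty and finite", call. = FALSE)
  }
  k <- switch(tail,
    one_greater = sum(nullStats >= observed),
    one_less = sum(nullStats <= observed),
    two = {
      mu <- mean(nullStats)
      sum(abs(nullStats - mu) >= abs(observed - mu))
    }
  )
  (1 + k) / (1 + length(nullStats))
}

#' Degree- and edge-length-preserving connectome rewiring
#'
#' Edges of the structural connectome are binned by the Euclidean distance
#' between their endpoints (equal-count bins over connected-edge lengths by
#' default). Within each bin, randomly selected pairs of edges are swapped
#' (a-b, c-d -> a-d, c-b or a-c, b-d); a swap is accepted only when it
#' creates no self-loop or multi-edge and both new edges fall in the same
#' distance bin, so every null preserves exactly the edge count, the binary
#' degree sequence and the per-bin edge counts. Weights travel with their
#' edges. Bins holding fewer than two edges are skipped with a notice.
#'
#' @param sc symmetric weighted structural connectome, zero diagonal.
#' @param geometry matching [ParcelGeometry-class].
#' @param nBins number of distance bins (default 10 deciles).
#' @param nNulls number of null networks.
#' @param seed integer seed.
#' @param swapFactor swap attempts per null as a multiple of the edge count
#'   (default 10).
#' @return A [RewiredEnsemble-class].
#' @export
rewirePreservingLength <- function(sc, geometry, nBins = 10, nNulls = 100,
                                   seed = 1, swapFactor = 10) {
  .checkSquareSymmetric(sc, "sc")
  if (nBins < 1) stop("nBins must be >= 1", call. = FALSE)
  n <- nrow(sc)
  d <- distanceMatrix(geometry)
  ut <- which(upper.tri(sc) & sc > 0)
  m <- length(ut)
  if (m < 2) stop("connectome has fewer than 2 edges", call. = FALSE)
  lens <- d[ut]
  binEdges <- unique(stats::quantile(lens, probs = seq(0, 1, length.out = nBins + 1)))
  binEdges[1] <- -Inf
  binEdges[length(binEdges)] <- Inf
  binOf <- matrix(findInterval(d, binEdges, left.open = TRUE), n, n)

  rows <- ((ut - 1) %% n) + 1
  cols <- ((ut - 1) %/% n) + 1
  edgeBin <- binOf[ut]
  small <- which(table(factor(edgeBin, seq_len(length(binEdges) - 1))) < 2)
  if (length(small)) {
    message("skipping ", length(small), " distance bin(s) with < 2 edges")
  }

  attempts <- swapFactor * m
  # Accepted swaps keep both replacement edges in the bin of the originals,
  # so each edge's bin is invariant and the per-bin pools can be fixed once.
  pools <- split(seq_len(m), edgeBin)
  mats <- vector("list", nNulls)
  nSwaps <- integer(nNulls)
  .withSeed(seed, {
    for (null in seq_len(nNulls)) {
      a <- rows; b <- cols; w <- sc[ut]; eb <- edgeBin
      adj <- matrix(FALSE, n, n)
      adj[cbind(a, b)] <- TRUE
      adj[cbind(b, a)] <- TRUE
      accepted <- 0L
      e1s <- sample.int(m, attempts, replace = TRUE)
      for (t in seq_len(attempts)) {
        e1 <- e1s[t]
        pool <- pools[[as.character(eb[e1])]]
        if (length(pool) < 2) next
        repeat {
          e2 <- pool[sample.int(length(pool), 1)]
          if (e2 != e1) break
        }
        x1 <- a[e1]; y1 <- b[e1]; x2 <- a[e2]; y2 <- b[e2]
        if (length(unique(c(x1, y1, x2, y2))) < 4) next
        # choose one of the two alternative pairings at random
        if (stats::runif(1) < 0.5) {
          n1 <- c(x1, y2); n2 <- c(x2, y1)
        } else {
          n1 <- c(x1, x2); n2 <- c(y1, y2)
        }
        if (adj[n1[1], n1[2]] || adj[n2[1], n2[2]]) next
        bb <- eb[e1]
        if (binOf[n1[1], n1[2]] != bb || binOf[n2[1], n2[2]] != bb) next
        adj[x1, y1] <- adj[y1, x1] <- FALSE
        adj[x2, y2] <- adj[y2, x2] <- FALSE
        adj[n1[1], n1[2]] <- adj[n1[2], n1[1]] <- TRUE
        adj[n2[1], n2[2]] <- adj[n2[2], n2[1]] <- TRUE
        a[e1] <- n1[1]; b[e1] <- n1[2]
        a[e2] <- n2[1]; b[e2] <- n2[2]
        accepted <- accepted + 1L
      }
      out <- matrix(0, n, n, dimnames = dimnames(sc))
      out[cbind(a, b)] <- w
      out[cbind(b, a)] <- w
      mats[[null]] <- out
      nSwaps[null] <- accepted
    }
  })
  new("RewiredEnsemble", matrices = mats, binEdges = as.numeric(binEdges),
      nSwaps = nSwaps, seed = as.integer(seed))
}

#' Connected-versus-unconnected similarity contrast
#'
#' Statistic: mean similarity over structurally connected region pairs minus
#' mean similarity over unconnected pairs (upper triangle). Significance is
#' assessed two-tailed against the same statistic computed on each rewired
#' null connectome, which preserves density, degree sequence and edge-length
#' binning.
#'
#' @param similarity symmetric region similarity matrix.
#' @param sc the empirical structural connectome the ensemble was built
#'   from.
#' @param ensemble a [RewiredEnsemble-class].
#' @return A list with `statistic`, `p` and `nullStats`.
#' @export
connectedContrastTest <- function(similarity, sc, ensemble) {
  .checkSquareSymmetric(similarity, "similarity")
  utIdx <- upper.tri(sc)
  simUT <- similarity[utIdx]
  stat <- .connContrast(sc[utIdx], simUT)
  nullStats <- vapply(nullMatrices(ensemble), function(m) {
    .connContrast(m[utIdx], simUT)
  }, numeric(1))
  list(statistic = stat, p = spinPvalue(stat, nullStats, "two"),
       nullStats = nullStats)
}

.connContrast <- function(scUT, simUT) {
  conn <- scUT > 0
  if (!any(!conn)) stop("no unconnected pairs", call. = FALSE)
  if (!any(conn)) stop("no connected pairs", call. = FALSE)
  mean(simUT[conn]) - mean(simUT[!conn])
}

#' Within- versus between-label similarity contrast
#'
#' Statistic: mean similarity of region pairs sharing a label (e.g. the
#' same intrinsic functional network) minus mean similarity of pairs with
#' different labels. The null spins the label map over the spherical
#' parcellation, preserving its spatial autocorrelation; when no spin
#' ensemble is available (e.g. incomplete cortical coverage), plain label
#' permutations are used instead.
#'
#' @param similarity symmetric region similarity matrix.
#' @param labels label per region; >= 2 distinct labels, none covering all
#'   regions.
#' @param spins a [SpinEnsemble-class], or `NULL` to fall back to plain
#'   permutations.
#' @param nPerm,seed permutation count and seed for the plain-permutation
#'   fallback (ignored when `spins` is given).
#' @return A list with `statistic`, `p` and `nullStats` (two-tailed).
#' @export
labelContrastTest <- function(similarity, labels, spins = NULL,
                              nPerm = 1000, seed = 1) {
  .checkSquareSymmetric(similarity, "similarity")
  labels <- as.vector(labels)
  if (length(unique(labels)) < 2) {
    stop("need >= 2 labels; one label covers all regions", call. = FALSE)
  }
  utIdx <- which(upper.tri(similarity))
  n <- nrow(similarity)
  rows <- ((utIdx - 1) %% n) + 1
  cols <- ((utIdx - 1) %/% n) + 1
  simUT <- similarity[utIdx]
  statFor <- function(lab) {
    within <- lab[rows] == lab[cols]
    mean(simUT[within]) - mean(simUT[!within])
  }
  stat <- statFor(labels)
  if (!is.null(spins)) {
    asn <- assignments(spins)
    nullStats <- vapply(seq_len(nrow(asn)), function(p) {
      statFor(labels[asn[p, ]])
    }, numeric(1))
  } else {
    nullStats <- .withSeed(seed, vapply(seq_len(nPerm), function(p) {
      statFor(sample(labels))
    }, numeric(1)))
  }
  list(statistic = stat, p = spinPvalue(stat, nullStats, "two"),
       nullStats = nullStats)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up BH adjustment with rejection at level `q`.
#'
#' @param pvalues numeric p-values in \[0, 1\].
#' @param q target false discovery rate (default 0.05).
#' @return A list with `rejected` (logical) and `adjusted` (monotone
#'   BH-adjusted p-values).
#' @export
fdrCorrect <- function(pvalues, q = 0.05) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(rejected = !is.na(adjusted) & adjusted <= q, adjusted = adjusted)
}
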
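---
title: "Linking receptor chemoarchitecture to connectome structure and function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking receptor chemoarchitecture to connectome structure and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoarch)
```

## The scientific problem

Neurotransmitter receptors and transporters are distributed heterogeneously
across the cortex, and their overlapping spatial topographies shape how
anatomically connected regions communicate, how population activity
oscillates, and which regions are recruited by which cognitive processes.
`chemoarch` implements the statistical machinery for interrogating a
parcel-resolved receptor density atlas — a region × receptor matrix of
z-scored densities — against connectomes, regional dynamics and behavioral
or clinical maps, together with the null models that such spatially
autocorrelated data demand.

Throughout, the atlas is held in a `ReceptorAtlas` (a
`SummarizedExperiment` with receptors as features and parcels as samples),
and the parcellation's centroids, spherical projection and hemisphere
labels in a `ParcelGeometry`. All analyses work purely on parcellated
tables; volumetric or surface image processing is out of scope.

## Descriptive structure of the atlas

**Receptor similarity** is the Pearson correlation between two regions'
receptor fingerprints. It decays approximately exponentially with the
Euclidean distance between region centroids; `fitDistanceDecay()` fits
`sim = a·exp(−b·d) + c` by Levenberg–Marquardt least squares with `b ≥ 0`,
initialized from a log-linear regression of the min-shifted similarity on
distance. The three-parameter form with an offset is a deliberate choice:
empirical similarity matrices rarely decay to zero, and the offset absorbs
the baseline without biasing the rate. A constant similarity matrix is
returned as the degenerate flat fit (`b = 0`) rather than an error.

The **principal receptor gradient** is the first principal component of
the z-scored matrix. Since PCA sign is arbitrary, the sign is fixed so the
sum of receptor loadings is positive, making downstream tests and
comparisons deterministic.

When several studies image the same receptor, `combineTracerMaps()`
z-scores each study map, averages with weights proportional to study
sample size, and re-z-scores. Absolute binding measures from different
studies and tracers are not commensurate, so averaging raw values would
let the largest-valued study dominate; averaging on the z-scale with
size-proportional weights is the natural compromise, and every downstream
analysis consumes z-scored maps anyway.

Sensitivity operations mirror standard robustness practice:
`looSimilarityRobustness()` recomputes similarity leaving each receptor
out, and `regressAge()` removes, region by region, the linear relationship
between densities and the mean participant age of each tracer study (the
only age information available when atlases are built from group-average
maps), re-z-scoring columns afterwards.

## Null models

Parcellated brain maps are spatially smooth, so naive permutation tests
are wildly anticonservative. Two null families are provided.

**Spin permutations** (`buildSpinEnsemble()`): each repetition draws a
rotation uniformly over SO(3), applies it to the left hemisphere's
spherical parcel coordinates and its x-mirrored conjugate to the right's,
and reassigns each parcel the value of the nearest rotated parcel of the
same hemisphere (ties to the lowest index; duplicate assignments are
allowed). Mirroring the rotation, rather than drawing hemispheres
independently, preserves inter-hemispheric symmetry: for a mirror-
symmetric parcellation the two hemispheres receive identical permutations.
A medial-wall marker carries no parcel value, so a parcel whose nearest
rotated point is the marker receives the next most proximal parcel — which
is what the nearest-*parcel* rule already yields. Permutation p-values use
`(1 + k)/(1 + N)`, so p is never exactly zero and the minimum is
`1/(N + 1)`.

**Length-binned rewiring** (`rewirePreservingLength()`): structural
connectome edges are binned by Euclidean length (equal-count deciles by
default — equal-width bins leave long-distance bins nearly empty), and
double-edge swaps are accepted only when both replacement edges fall in
the bin of the originals and create no self-loop or multi-edge. Every null
therefore preserves *exactly* the edge count, binary degree sequence and
per-bin edge counts; weights travel with their edges. Swap attempts
default to 10× the edge count per null; the same-bin constraint rejects
most proposals, but the accepted swaps (typically a few hundred on a
100-region, 990-edge network) are sufficient to decorrelate topology, as
the calibration tests verify.

## Structure–function coupling and receptor augmentation

Communicability weights all walks between two regions by the inverse
factorial of their length: `expm(S^(−1/2) A S^(−1/2))` with `S` the
diagonal strength matrix. The strength normalization is required for
weighted networks — the raw matrix exponential diverges with weight
scale. Per region, structure–function coupling is the adjusted R² of a
simple regression of the region's functional connectivity profile on its
communicability profile (self-connection excluded, intercept included,
n − 1 observations). The augmentation test adds the region's receptor
similarity profile as a second predictor and compares the augmented
adjusted R² one-sided against refits with spun similarity profiles,
BH-FDR-corrected across regions. The null is built on the augmented R²
itself (not the increment): the spun predictor carries the same spatial
autocorrelation as the real one, so the comparison isolates the
receptor-specific contribution.

## Multilinear models, dominance, and cross-validation

`fitMultilinear()` is OLS with intercept of a regional map on all receptor
densities, reporting R² and adjusted R². Model significance compares the
observed adjusted R² against refits on spun outcome maps; spinning the
outcome rather than the predictor block is equivalent for model fit under
row permutation and considerably cheaper.

**Dominance analysis** decomposes the full-model R² into per-predictor
contributions: the total dominance of predictor *k* is the average over
subset sizes of its mean incremental R² across all submodels lacking *k*.
All `2^p − 1` subset R² values are computed from one precomputed
correlation matrix in compiled code (per-subset Cholesky solves, with a
pseudo-inverse fallback so duplicated or collinear predictors are handled
rather than rejected; at p = 19 the enumeration takes seconds). The
identity `Σ dominance = R²` holds exactly on the unadjusted R² and is
asserted in the result constructor. Percent shares are reported normalized
both by R² and by adjusted R²: the averaging definition operates on R²
increments, while fits are conventionally reported as adjusted R², so both
normalizations are emitted and the R²-based one carries the exact-sum
guarantee.

**Distance-dependent cross-validation** assigns every region once as a
source node; the `⌈0.75 n⌉` regions nearest the source (the source
included, keeping the split a clean 75/25 partition) train the model and
the rest test it. Out-of-sample performance is the Pearson correlation
between predicted and observed test values. Because training and test
sets are spatially segregated, this is a far sterner test than random
folds for smooth maps.

## PLS correlation

`plsDecompose()` takes the SVD of the cross-covariance `XᵀY/(n − 1)` of
two column-z-scored blocks (with standardized columns this equals the
cross-correlation). Squared singular values, as fractions of their sum,
give the covariance explained per latent variable. Latent-variable signs
are fixed so each X score correlates positively with the regional mean
receptor density. Significance is assessed on the singular values against
re-decompositions with spun X rows — no Procrustes alignment of null
singular vectors, since only the values are compared. In the distance CV
for PLS, each fold decomposes the training block and projects held-out
rows onto the training LV1 weights after centering them by training-set
means (train-mean centering is the standard choice; rescaling by training
standard deviations changes test correlations only marginally since the
global columns are already standardized).

## The synthetic cortex and what it does (and does not) emulate

The generator module produces data with planted, recorded ground truth:

- **Geometry** (`generateParcellation`): a Fibonacci lattice per
  hemisphere on a unit sphere, one seed-derived random rotation (mirrored
  across hemispheres), hemisphere spheres of radius `0.4·radius` centered
  at `±0.6·radius` (defaults: 28 mm spheres, 140 mm total span — Euclidean
  distances in the range of a human cortex). Two design points matter.
  First, within a hemisphere, centroid distance is exactly proportional to
  chordal sphere distance, so spherical rotations preserve the
  within-hemisphere distance structure that the spin test relies on.
  Second, the 28 mm inter-hemispheric gap bounds cross-hemisphere
  correlation (at the default 20 mm length scale) to about 0.25:
  hemisphere-separate spins cannot preserve non-mirror cross-hemisphere
  covariance, and a geometry with near-touching midline parcels would bake
  that method assumption violation into every calibration study.
- **Regional maps** (`sampleSAMap`): zero-mean Gaussian fields with
  covariance `σ²·exp(−d/λ)` over centroid distances (default λ = 20 mm),
  the covariance symmetrized and diagonally jittered by `1e−10·trace/n`
  before Cholesky factorization.
- **Atlases** (`generateReceptorAtlas`): receptor maps are mixtures of
  `nLatent` spatially autocorrelated latent maps plus independent noise,
  then z-scored. Mixing weights are scaled orthonormal rows of a random
  orthogonal matrix rather than dense Gaussian draws: Gaussian mixing
  induces strong receptor–receptor correlation beyond the shared latent
  span, which makes planted active sets unidentifiable for *any*
  importance measure — dominance analysis deliberately shares credit
  among collinear predictors. The recorded gradient is the first
  principal component of the noiseless mixture.
- **Connectomes** (`generateConnectomes`): structural edges sampled
  without replacement with probability `exp(−d/30 mm)` until the target
  density (default 0.2), weights uniform on (0.1, 1] (strictly positive,
  as strength normalization requires); the functional connectome is the
  z-scored communicability plus `couplingBeta` times a supplied receptor
  similarity matrix plus symmetric Gaussian noise, so the augmentation
  test has a planted, recoverable effect.
- **Targets and paired blocks**: target maps are weighted sums of a chosen
  active receptor set with noise scaled to a requested signal-to-noise
  variance ratio; the paired "cognitive" block shares the atlas's
  principal gradient at a chosen strength `latentCorr`, the rest being
  independent spatially autocorrelated noise.

The geometry is a stylized sphere pair: no cortical folding, no laminar
structure, no realistic receptor covariance, and cross-hemisphere
covariance is weaker than in real data by construction. Consequently,
passing calibration and recovery tests here demonstrates that the
*machinery* is correct and calibrated under its own assumptions — not that
real receptor atlases satisfy those assumptions.

## Numerical choices and problem sizes

Z-scoring uses the sample standard deviation throughout, and zero-variance
inputs are errors, not silent drops. Regression fits go through QR;
two-predictor regional fits use the closed-form R² from pairwise
correlations with a collinearity guard that falls back to the
single-predictor fit. The test suite and the benchmark script run at the
scale of 100 regions, 12–19 receptors, 300–1,000 spins, 100 rewired nulls,
and 20–500 replicate datasets per calibration study — sizes chosen so the
full suite completes in a few minutes on a single core while keeping
Monte-Carlo error well inside the asserted tolerances. Seeds fan out from
a single integer into independent substreams, and regeneration under the
same seed is bit-identical.

## Known limitations

- The spin test preserves within-hemisphere autocorrelation but only the
  mirror-symmetric part of cross-hemisphere structure; its calibration on
  data with strong non-mirror cross-hemisphere covariance is not
  guaranteed (this drove the gap in the synthetic geometry).
- Dominance analysis is enumerative: p is capped (default 20) and credit
  among strongly collinear receptors is shared, not attributed.
- The decay fit assumes a single global exponential; spatially
  heterogeneous decay rates are averaged.
- The pipeline driver consumes already-parcellated tables only; image
  registration, tractography, and meta-analytic map construction are
  upstream concerns.
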
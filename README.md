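# chemoarch

Cortical **chemoarchitecture** — the spatial organization of
neurotransmitter receptor and transporter densities across the cortex — is
a key layer between brain structure and brain function. `chemoarch` is an R
package for analyzing parcellated receptor density atlases against
connectome structure, regional dynamics and behavioral maps. It is aimed at
systems and network neuroscientists working with parcel-resolved imaging
derivatives (region × receptor density tables, dense structural/functional
connectomes, regional scalar maps).

## What it computes

Given a region × receptor matrix of z-scored densities **X** (regions *n*,
receptors *p*) and the geometry of the parcellation:

- **Receptor similarity**: the region × region matrix of Pearson
  correlations between receptor fingerprints, its approximately exponential
  decay with Euclidean centroid distance (`sim = a·e^(−b·d) + c`, fit by
  nonlinear least squares), and its first principal component — the
  principal receptor gradient.
- **Null models**: spatial-autocorrelation-preserving *spin* permutations
  (random SO(3) rotations of the spherical parcel projection, hemispheres
  rotated as mirror images, values reassigned from the nearest rotated
  parcel) and degree-, density- and edge-length-preserving connectome
  rewiring (double-edge swaps restricted to edges in the same distance
  bin). Permutation p-values use the (1+k)/(1+N) convention;
  Benjamini–Hochberg FDR across regions or models.
- **Structure–function coupling**: weighted communicability
  `exp(S^(−1/2) A S^(−1/2))` of the structural connectome; per-region
  adjusted R² of functional connectivity profiles regressed on
  communicability profiles; and the *receptor augmentation* test — whether
  adding the region's receptor-similarity profile improves the fit more
  than a spun profile would.
- **Multilinear models + dominance analysis**: OLS prediction of a regional
  map (oscillatory band power, disorder abnormality, …) from all receptor
  densities; spin-based model significance; and full-subset **dominance
  analysis** — the model's R² decomposed over predictors by averaging
  incremental R² across all 2^p − 1 submodels (enumerated in compiled
  code; exact identity `Σ dominance = R²` asserted).
- **PLS correlation**: SVD of the cross-covariance `XᵀY/(n−1)` between the
  receptor block and a region × term matrix; latent-variable covariance
  explained, region scores, feature loadings, spin significance on the
  singular values.
- **Distance-dependent cross-validation**: every region serves once as a
  source node; its 75% nearest regions train the model and the remaining
  25% test it, limiting inflation from spatial autocorrelation.
- **Synthetic data with planted ground truth** (`generateParcellation`,
  `sampleSAMap`, `generateReceptorAtlas`, `generateConnectomes`,
  `generateTargetMaps`, `generatePairedMatrix`): a stylized two-hemisphere
  geometry, Gaussian fields with exponential spatial covariance, planted
  gradients, active receptor sets, receptor→FC coupling and shared latent
  components — so every inferential stage is testable without external
  imaging data.

## Worked example

```r
library(chemoarch)

geom  <- generateParcellation(100, seed = 1)          # 50 + 50 regions
ra    <- generateReceptorAtlas(geom, nReceptors = 19, nLatent = 19,
                               noiseSd = 0.2, seed = 2)
atlas <- ra$atlas
sim   <- receptorSimilarity(atlas)
fitDistanceDecay(sim, geom)
#> DecayFit: similarity = 1.1468 * exp(-0.0563 * d) + -0.1039  (rss 244, 4950 pairs)

# a map driven by three receptors, recovered by dominance analysis
tm  <- generateTargetMaps(atlas, activeSet = c("R01", "R05", "R09"),
                          snr = 10, seed = 3)
dom <- dominance(atlas, tm$maps[, 1])
dom
#> DominanceResult over 19 predictors (full-model R2 = 0.949)
#>   leading shares (% of R2): R05 54.3, R09 21.7, R01 11.2

spins <- buildSpinEnsemble(geom, 1000, seed = 4)
spinModelSignificance(atlas, tm$maps[, 1], spins)$p
#> [1] 0.000999001
```

The decay fit says receptor similarity falls off with a length scale of
roughly 1/0.056 ≈ 18 mm on this synthetic cortex; the dominance shares
place the three planted receptors first (~87% of the model fit between
them); and the spin test finds the multilinear model far beyond what
spatially autocorrelated chance produces (minimum attainable p at 1,000
rotations).

An end-to-end driver is available as `runPipeline(config)`, where `config`
is a list or YAML file naming the input tables (geometry, atlas, optional
connectomes, target maps, term matrix); it writes stage TSVs and a
machine-readable JSON report.

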
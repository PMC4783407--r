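---
title: "Methods: random-forest segregation of phMRI connectivity profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-forest segregation of phMRI connectivity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`forestconn` allocates individual subjects to pharmacological treatment arms
from resting/infusion fMRI, and backtracks the allocation to named brain
region pairs. This vignette documents the model, the tunable parameters, the
synthetic world the tests run in, the numerical choices, and the known
limitations — including one acceptance criterion that is deliberately left
failing.

## The pipeline and its assumptions

Per subject, the input is a set of R region-of-interest (ROI) blocks, each a
T × V matrix (timepoints × voxels). The pipeline assumes all subjects share
the ROI set and T, that series contain no missing values, and that group
labels are known for training (supervised setting).

**1. Dimensionality reduction.** Each ROI block is embedded with timepoints
as samples and voxels as features, producing a T × d "reduced time course"
(d = 1 by default, so downstream correlation is the ordinary scalar-series
correlation; with d > 1 the T·d matrix is flattened before correlating).
Nothing in the source procedure fixes what the embedding should operate on;
this orientation is the only one that yields a *reduced time series* per ROI,
which the downstream correlation step requires. Methods: PCA
(`stats::prcomp`), isomap (k-nearest-neighbour graph, geodesic distances via
`igraph::distances`, classical MDS; disconnected graphs are bridged by the
shortest Euclidean edge between components), t-SNE (`Rtsne`, exact,
seeded), and locally-linear embedding (implemented in-package). Embedding
signs are arbitrary, but correlation features are sign-sensitive; every
component is therefore flipped to correlate non-negatively with the ROI's
mean voxel time course, then z-scored. A one-voxel ROI needs no embedding
and is returned z-scored by every method.

**2. Feature-vector preprocessing.** The reduced course is high-pass
filtered, then column-standardized (in that order). The described filter
("high pass ... to smooth") is contradictory as written; it is implemented
as subtraction of a centered moving-average baseline — a high-pass filter
whose complement is the smooth baseline. At the edges the window shrinks
*symmetrically* (half-width `min(floor(window/2), t-1, T-t)`), which makes
the baseline exact on any linear trend: a ramp maps to zero everywhere, and
drift of the kind the generator plants is removed rather than smeared into
the correlations. The window is configurable (`highpass_window`), defaults
to T/4, and can be bypassed (`NULL`). Standardization uses the sample (n−1)
standard deviation and refuses constant columns by name.

**3. Connectivity features.** All R(R−1)/2 unordered ROI pairs are
correlated (Pearson) and Fisher z-transformed,
z = ½·log[(1+ρ)/(1−ρ)], the standard variance-stabilizing transform (the
source's "fitted to a Gaussian curve" is read as exactly this intent — no
additional fitting is performed). |ρ| is clipped at 1 − 10⁻⁷ so degenerate
(perfectly correlated) synthetic fixtures stay finite. The upper triangle is
flattened row-major with 1-based feature ids; `pair_to_index()` /
`index_to_pair()` form the bijection used everywhere for backtracking, and
45 ROIs give the canonical 990 features.

**4. Random-forest classification with an abstention band.** The forest is
bagged CART with per-node random feature subsampling (Gini criterion),
implemented in the package (`src/forest.cpp`): no random-forest engine is
available in the target environment, and the importance definition below
needs per-tree votes and in-bag masks exposed anyway. Defaults: 500 trees,
`mtry = floor(sqrt(p))`, `min_leaf = 1` — the conventional defaults of the
classification forest the source procedure cites. Under leave-one-out (LOO)
cross-validation each held-out subject receives the fraction of trees voting
for its true group; outcomes are
*correct* (p > 0.55), *false* (p < 0.45), and *unclassified* (0.45 ≤ p ≤
0.55, boundaries inclusive — boundary mass is measure-zero in practice but
must be deterministic). In prediction mode (truth unknown) the max-vote class
is reported with the same band. Every run draws its per-fold seeds from one
master seed, so all bootstrap draws, split samplings and permutations are
reproducible.

**5. Importance and nested selection.** Variable importance is the
out-of-bag *permutation* importance: for each tree, the increase of its OOB
error when one feature's OOB values are permuted, averaged over trees.
Features a tree never splits on contribute exactly zero for that tree (and
are skipped — an identical-by-construction optimization), so constant
features score exactly 0. Ranks break ties by ascending feature index. The
re-evaluation step selects the top k = 10 features and refits — with
importance computed *per fold on training subjects only*, so the held-out
row can never influence selection (tests corrupt it with sentinels and
assert bit-identical training behaviour). The *consensus subset* reports
features selected in ≥ 50% of folds (the source reports a single subset
without stating fold aggregation; 50% is this package's choice). `k_sweep()`
reproduces the robustness check that accuracy decays as weak features are
added back.

**6. Dose-vs-dose contrast.** When direct classification of the two dose
arms carries no signal, features are taken from the two control comparisons:
the default keeps ROI *pairs* present in exactly one of the two consensus
subsets (symmetric difference — the stricter, more reproducible reading of
"uncommon correlation pairs"); `mode = "region"` instead keeps pairs
touching an anatomical region that appears in only one comparison's region
set (the Results-paragraph reading). As published, this selection uses all
subjects of the two control comparisons and is *not* nested inside the dose
contrast's own LOO; subjects of the dose arms appear in those control
comparisons, so a strict no-reuse reading would call this leakage across
comparisons. It is implemented as published and flagged here.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `n_components` (d) | 1 | — | scalar-series correlation downstream |
| `n_neighbors` | 10 | timepoints | isomap/LLE graph; < T required |
| `perplexity` | 15 | — | t-SNE; clamped to (T−1)/3 for small T |
| `highpass_window` | T/4 | timepoints | slow-drift scale at TR 2.5 s |
| `n_trees` | 500 | — | conventional forest default |
| `mtry` | ⌊√p⌋ | features | conventional classification default |
| band | [0.45, 0.55] | vote fraction | stated abstention band |
| `k` | 10 | features | stated top-k rule |
| consensus threshold | 0.5 | fraction of folds | package choice (see above) |
| region aggregation | max | — | one score per region; rule recorded |
| display threshold | 2.0 | importance | presentational "<2" convention |

## The synthetic world

`generate_dataset()` draws, per subject, a zero-mean multivariate-normal
latent signal across ROIs whose correlation matrix has `base_corr = 0.1`
off-diagonal; *planted edges* get `tanh(atanh(base_corr) + effect_dz[group])`
— effects compose additively on the Fisher-z scale, so the default
`effect_dz` (saline 0, LD 0.5, HD 1.0) is dose-ordered by construction. The
matrix is repaired to positive definiteness by eigenvalue clipping at 10⁻⁶
and re-normalization to unit diagonal (a no-op for the default disjoint
edges). Each voxel series is latent + N(0, `voxel_noise_sd` = 1) noise,
passed through a variance-preserving AR(1) filter (`ar1_coef` = 0.3, typical
fMRI temporal autocorrelation; the same filter on all series leaves zero-lag
correlations unchanged in expectation) with an added per-voxel linear drift
(`drift_amplitude` = 0.5 — present so the high-pass stage has something real
to remove). Defaults mirror the emulated study: 13/12/12 subjects, 45 ROIs,
600 timepoints, TR 2.5 s, 20 voxels per ROI, five planted edges among the
first ten regions. The default atlas carries the lateralized structures
relevant to opioid pharmacology (hippocampus, amygdala, thalamus, accumbens,
colliculi, ...) padded with generic bilateral pairs to 45.

What the generator does **not** emulate: between-subject variability beyond
sampling noise (no random subject effects on connectivity), hemodynamics and
drug kinetics (no onset/washout dynamics — effects are stationary), spatial
structure within ROIs, motion, and physiological noise. A green planted-
signal test therefore establishes that the pipeline recovers stationary
connectivity differences at realistic n/T/SNR — not that it would survive
real-data confounds.

Whether the original series entering the pipeline were multi-voxel or
ROI-averaged is not stated in the source; the generator produces multi-voxel
blocks so both readings are exercisable (a one-voxel block short-circuits
the reduction).

## Numerical choices

- Fisher clipping 10⁻⁷; z agrees with `atanh` to 10⁻¹² on (−0.999, 0.999).
- PD repair: eigenvalue floor 10⁻⁶, then unit-diagonal re-normalization;
  unrepairable matrices raise an error rather than sampling from a broken
  world.
- Importance ties → ascending feature index; leaf-class ties → lowest class
  index; vote ties in prediction → first factor level. All deterministic.
- LLE local Gram regularization: 10⁻³ · trace, the standard Roweis–Saul
  conditioning.
- Isomap on fragmented kNN graphs: components bridged by the shortest
  Euclidean edge (repeatedly), so every timepoint is embedded.
- Voxel order within an ROI is irrelevant by construction (embeddings are
  permutation-equivariant up to sign, fixed by the mean-series convention);
  extraction from labelled volumes orders voxels lexicographically by
  (x, y, z) for reproducibility.

## Known limitations and the deliberate red test

**Leave-one-out class-prior bias (acceptance criterion 4, red).** On
null data (no planted effect, groups of 13 vs 12) the suite checks whether
the fraction of *correct* among *classified* subjects is consistent with
0.5. It is not — measured ≈ 0.18 over 20 seeds — and the failure is left in
place because it is a property of the published procedure, not of this
implementation. Holding out a subject from the smaller group leaves a 13/11
training set; a majority-vote tree trained on pure-noise features votes for
the true class with probability ≈ its training share (11/24), so the
expected vote fraction is ≈ 0.479 (measured 0.483). The [0.45, 0.55] band
then removes the symmetric middle of the vote distribution, and the
classified remainder falls predominantly below 0.45. Any uniform-bootstrap
majority-vote classifier behaves this way under LOO; fixing it would require
stratified bootstrap or class-prior correction, both deviations from the
procedure as described. Practical reading: *below-chance LOO accuracy on a
null contrast is expected, not evidence of anti-signal*.

**Vote saturation at very small n.** With 3 training subjects, ~30% of
bootstrap samples miss the singleton class entirely and any noise feature
isolating that subject ties the informative features on Gini decrease, so
vote fractions cannot saturate; N = 4 LOO runs, but "all correct" outcomes
begin to be achievable only at slightly larger n (the suite demonstrates
saturation at 6 vs 6).

**t-SNE as a time-course reducer.** A 1-D stochastic-neighbour embedding
preserves local neighbourhoods, not global temporal order; even on strongly
separated groups it can leave a subject in the abstention band or flip one
— consistent with it being the weakest method in the source's comparison.
The comparison harness (`compare_reduction_methods()`) reproduces the
qualitative ordering: on monotone-nonlinearly mixed voxels (each voxel a
distinct warp — tanh, power, exp, asinh, logistic — of the latent signal),
isomap's correct count is ≥ PCA's in ≥ 7/10 fixed seeds. That fixture is
deliberately off-ceiling (planted Fisher-z effect 0.3, inner noise 0.8) so the
comparison discriminates; at saturating effect sizes all methods tie.

**Scope.** Motion correction, smoothing, registration, atlas construction,
GLM analysis and receptor-biology interpretation are out of scope; inputs
are assumed preprocessed. Multi-class (> 2 group) classification is not
offered — the procedure is pairwise by design. NIfTI ingestion is limited to
in-memory 4D arrays (`extract_roi_series()`); no on-disk NIfTI reader is
available in the target environment.
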
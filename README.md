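# forestconn

Random-forest segregation of treatment groups from pharmacological fMRI
functional connectivity.

## The problem

Pharmacological MRI (phMRI) records whole-brain time series while a drug is
infused. For a CNS compound the interesting questions are *can individual
subjects be allocated to their treatment arm from the response alone*, and
*which brain regions carry that discrimination*? Model-based analysis (GLM)
needs a temporal response model, which is exactly what is unknown for a novel
compound. `forestconn` implements a model-free pipeline for this setting,
built for the three-arm design it emulates (vehicle/saline, low dose, high
dose; e.g. an opioid analgesic study in rodents with 45 atlas regions and
600 volumes at TR = 2.5 s):

1. **Reduction** — each region-of-interest's (ROI) voxel × time block is
   reduced to a low-dimensional time course, treating timepoints as samples
   and voxels as features (isomap by default; PCA, t-SNE and LLE for
   comparison), then high-pass filtered (centered moving-average baseline
   subtraction) and standardized.
2. **Connectivity** — all pairwise Pearson correlations between reduced ROI
   time courses,
   `rho(X,Y) = E[(X - mu_X)(Y - mu_Y)] / (sigma_X sigma_Y)`,
   are variance-stabilized by the Fisher z-transformation
   `z = 0.5 * log((1 + rho) / (1 - rho))` and flattened into a feature
   vector of length R(R-1)/2 (45 ROIs → 990 features) with a bijective
   feature ↔ ROI-pair index, so every feature backtracks to a named,
   lateralized region pair.
3. **Classification** — a bagged random forest (per-node feature
   subsampling, Gini splits) under leave-one-out (LOO) cross-validation.
   Each held-out subject is scored by the fraction of trees voting for its
   true group; vote fractions inside **[0.45, 0.55]** are reported as
   *unclassified* rather than forced to a label.
4. **Selection** — out-of-bag permutation importance (the mean increase of a
   tree's OOB error when one feature's values are permuted) ranks the ROI
   pairs; the top k = 10 are re-classified *inside* the LOO loop (selection
   is recomputed per fold from training subjects only). For the
   dose-vs-dose contrast, features are taken from the *symmetric difference*
   of the two control-comparison subsets — pairs important in exactly one of
   saline-vs-LD / saline-vs-HD.
5. **Reporting** — Table-style outcome counts (correct / false /
   unclassified / k), region-level importance with a `"<2"` display
   threshold, TSV outputs with provenance headers, and a YAML-configured CLI
   (`simulate`, `run`, `compare-reductions`, `sweep-k`).

A synthetic-data module generates multi-subject ROI time series from a
multivariate-normal latent model with group effects planted on the Fisher-z
scale of chosen ROI pairs (dose-ordered by default), plus per-voxel noise,
AR(1) temporal autocorrelation and scanner drift — so the whole pipeline is
testable without any imaging data.

## Worked example

```r
library(forestconn)

cfg <- synth_config(n_rois = 12, n_timepoints = 150, voxels_per_roi = 8,
                    group_sizes = c(saline = 7, LD = 6, HD = 6),
                    planted_edges = cbind(c(1, 3, 5), c(2, 4, 6)),
                    effect_dz = c(saline = 0, LD = 0.8, HD = 1.6),
                    seed = 7)
dataset <- generate_dataset(cfg)
fm <- dataset_feature_matrix(dataset, reduction_params("isomap"))
fm
#> <feature_matrix> 19 subjects x 66 Fisher-z features; groups: HD=6, LD=6, saline=7

fm_hd <- subset_subjects(fm, c("saline", "HD"))
loo_classify(fm_hd, forest_params(n_trees = 500, seed = 7))$summary
#>   comparison correct false unclassified  k  accuracy
#> 1       <NA>      10     0            3 13 0.7692308

nested <- nested_loo_with_selection(fm_hd, k = 10,
                                    params = forest_params(n_trees = 500,
                                                           seed = 7))
nested$summary
#>   comparison correct false unclassified  k accuracy
#> 1       <NA>      13     0            0 13        1
head(nested$consensus, 3)[, c("feature_id", "region_i", "region_j",
                              "fold_frequency")]
#>   feature_id region_i region_j fold_frequency
#> 1         22        3        4              1
#> 2          1        1        2              1
#> 3         39        5        6              1
```

Reading this output: with all 66 features, 10 of 13 subjects are correctly
allocated and 3 fall in the unclassified band (no false allocations);
restricting each fold to its own top-10 important features sharpens the
votes to 13/13. The consensus subset (features selected in ≥ 50% of folds)
recovers exactly the three planted ROI pairs — features 1, 22 and 39 are
the pairs (1,2), (3,4), (5,6) — each selected in every fold.

The full pipeline, including the three pairwise comparisons and the
mutually-exclusive dose contrast, runs from a single config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "forestconn"))
```

or from the shell via the bundled launcher:

```sh
Rscript inst/exec/forestconn run --config inst/extdata/demo_config.yaml
```

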
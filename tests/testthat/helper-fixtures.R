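# Shared fixtures, all generated in code (no stored data).

# Small two-group dataset with a strong planted effect: separable in a few
# seconds of compute.
toy_dataset <- function(seed = 42, effect = 1.5, n_rois = 8, T = 120, V = 5,
                        n_a = 6, n_b = 6) {
  cfg <- synth_config(
    n_rois = n_rois, n_timepoints = T, voxels_per_roi = V,
    group_sizes = c(saline = n_a, HD = n_b),
    planted_edges = cbind(c(1, 3), c(2, 4)),
    effect_dz = c(saline = 0, HD = effect), seed = seed)
  generate_dataset(cfg)
}

# Plain feature matrix without any synthesis: n subjects split into two
# groups, p noise features, plus optional informative columns.
toy_feature_matrix <- function(n = 20, p = 50, seed = 1, delta = 0,
                               informative = integer(0)) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(c("A", "B"), length.out = n)
  for (j in informative) x[y == "B", j] <- x[y == "B", j] + delta
  rownames(x) <- sprintf("s%02d", seq_len(n))
  n_rois <- ceiling((1 + sqrt(1 + 8 * p)) / 2)
  pairs <- pair_index(n_rois)[seq_len(p), ]
  pairs$name <- paste0("roi", pairs$region_i, "|roi", pairs$region_j)
  colnames(x) <- pairs$name
  structure(list(x = x, groups = factor(y), pairs = pairs, atlas = NULL),
            class = "feature_matrix")
}

# Monotone nonlinear voxel mixing on top of a latent-only dataset: each voxel
# is a distinct monotone warp of (latent + small inner noise) plus a little
# output noise. Exercises the advantage of geodesic embeddings over PCA.
warp_bank <- list(
  function(x) x,
  function(x) tanh(1.5 * x),
  function(x) sign(x) * sqrt(abs(x)),
  function(x) x^3 / 3,
  function(x) exp(x) / exp(1),
  function(x) asinh(2 * x),
  function(x) plogis(2 * x) * 4,
  function(x) sign(x) * abs(x)^1.5
)

nonlinear_mixed_dataset <- function(seed, n_rois = 10, T = 150, V = 8,
                                    n_a = 10, n_b = 10, effect = 0.3,
                                    inner_sd = 0.8, outer_sd = 0.2) {
  cfg <- synth_config(
    n_rois = n_rois, n_timepoints = T, voxels_per_roi = 1,
    group_sizes = c(saline = n_a, HD = n_b),
    planted_edges = cbind(c(1, 3, 5), c(2, 4, 6)),
    effect_dz = c(saline = 0, HD = effect),
    voxel_noise_sd = 0, ar1_coef = 0, drift_amplitude = 0, seed = seed)
  ds <- generate_dataset(cfg)
  set.seed(seed + 77)
  ds$subjects <- lapply(ds$subjects, function(sub) {
    sub$series <- lapply(sub$series, function(m) {
      latent <- m[, 1]
      vox <- vapply(seq_len(V), function(v) {
        g <- warp_bank[[(v - 1) %% length(warp_bank) + 1]]
        g(latent + rnorm(T, sd = inner_sd)) + rnorm(T, sd = outer_sd)
      }, numeric(T))
      vox
    })
    sub
  })
  ds
}

# Importance ranking built straight from scores (independent of any forest).
ranking_from_scores <- function(importance, pairs = NULL) {
  forestconn:::make_importance_ranking(importance, pairs)
}
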
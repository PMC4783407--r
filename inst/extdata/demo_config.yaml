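# Demo configuration: small synthetic three-group study (scaled down from
# the default 45 ROIs x 600 timepoints so it runs in seconds).
output_dir: forestconn_demo
seed: 7
data:
  source: synthetic
  synthesis:
    n_rois: 12
    n_timepoints: 150
    voxels_per_roi: 8
    group_sizes: {saline: 7, LD: 6, HD: 6}
    planted_edges: [[1, 2], [3, 4], [5, 6]]
    effect_dz: {saline: 0.0, LD: 0.8, HD: 1.6}
reduction:
  method: pca
  n_components: 1
  highpass_window: auto
  standardize: true
classification:
  n_trees: 200
  band: [0.45, 0.55]
selection:
  k: 5
  control_group: saline
report:
  aggregate: max
  display_threshold: 2.0
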
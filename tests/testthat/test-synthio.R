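test_that("atlas labels are unique, contiguous, and lateralized", {
  a <- make_atlas_labels(45)
  expect_equal(nrow(a), 45)
  expect_equal(a$region_id, 1:45)
  expect_equal(anyDuplicated(paste(a$name, a$side)), 0L)
  expect_true(all(c("left", "right") %in% a$side[a$name == "hippocampus"]))
  # every lateralized name appears with both sides
  lat <- a[a$side != "midline", ]
  expect_true(all(table(lat$name, lat$side) <= 1))
  for (nm in unique(lat$name))
    expect_setequal(lat$side[lat$name == nm], c("left", "right"))
  expect_equal(nrow(make_atlas_labels(2)), 2)
  expect_error(make_atlas_labels(1), "at least 2")
})

test_that("default dataset matches the emulated study geometry", {
  cfg <- synth_config(n_timepoints = 8, voxels_per_roi = 1) # scaled T only
  ds <- generate_dataset(cfg)
  grp <- vapply(ds$subjects, `[[`, character(1), "group")
  expect_equal(length(ds$subjects), 37) # 13 saline + 12 LD + 12 HD
  expect_equal(as.integer(table(grp)[c("saline", "LD", "HD")]),
               c(13L, 12L, 12L))
  expect_equal(length(ds$subjects[[1]]$series), 45)
  expect_equal(ds$tr, 2.5)
  full <- synth_config()
  expect_equal(full$n_timepoints, 600L)
  expect_equal(unname(full$effect_dz[c("saline", "LD", "HD")]),
               c(0, 0.5, 1.0)) # dose-ordered
})

test_that("generation is deterministic given the config seed", {
  cfg <- synth_config(n_rois = 4, n_timepoints = 20, voxels_per_roi = 2,
                      group_sizes = c(saline = 2, HD = 2),
                      planted_edges = cbind(1, 2),
                      effect_dz = c(saline = 0, HD = 1), seed = 9)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$subjects, d2$subjects)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(generate_dataset(cfg2)$subjects, d1$subjects))
})

test_that("config validation rejects invalid worlds", {
  expect_error(synth_config(n_trees = 1), "unused argument")
  expect_error(synth_config(planted_edges = cbind(1, 99)), "invalid ROI")
  expect_error(synth_config(planted_edges = cbind(3, 3)), "distinct")
  expect_error(synth_config(base_corr = 1), "base_corr")
  expect_error(synth_config(group_sizes = c(5, 5)), "named")
  expect_error(synth_config(ar1_coef = 1), "ar1_coef")
  expect_error(synth_config(group_sizes = c(a = 3, b = 3),
                            effect_dz = c(a = 0)), "every group")
})

test_that("zero effect leaves no group difference on planted edges", {
  cfg <- synth_config(n_rois = 6, n_timepoints = 200, voxels_per_roi = 1,
                      group_sizes = c(saline = 13, HD = 12),
                      planted_edges = cbind(c(1, 3), c(2, 4)),
                      effect_dz = c(saline = 0, HD = 0),
                      voxel_noise_sd = 0, ar1_coef = 0, drift_amplitude = 0,
                      seed = 21)
  ds <- generate_dataset(cfg)
  z_edge <- function(sub, i, j)
    fisher_z(pearson_cor(sub$series[[i]][, 1], sub$series[[j]][, 1]))
  z <- t(vapply(ds$subjects, function(s)
    c(z_edge(s, 1, 2), z_edge(s, 3, 4)), numeric(2)))
  grp <- vapply(ds$subjects, `[[`, character(1), "group")
  dz <- colMeans(z[grp == "HD", ]) - colMeans(z[grp == "saline", ])
  se <- sqrt(1 / 12 + 1 / 13) / sqrt(200 - 3)
  expect_true(all(abs(dz) < 3 * se))
})

test_that("planted Fisher-z effect is recovered on latent signals", {
  # Monte-Carlo oracle: per-subject z ~ Normal(atanh(rho_g), 1/(T-3));
  # with 50 subjects the group mean has SE 1/(sqrt(T-3) sqrt(50)).
  cfg <- synth_config(n_rois = 4, n_timepoints = 600, voxels_per_roi = 1,
                      group_sizes = c(HD = 50), planted_edges = cbind(1, 2),
                      effect_dz = c(HD = 1.0), base_corr = 0.1,
                      voxel_noise_sd = 0, ar1_coef = 0, drift_amplitude = 0,
                      seed = 33)
  ds <- generate_dataset(cfg)
  z <- vapply(ds$subjects, function(s)
    fisher_z(pearson_cor(s$series[["1"]][, 1], s$series[["2"]][, 1])),
    numeric(1))
  se <- 1 / sqrt(600 - 3) / sqrt(50)
  expect_lt(abs(mean(z) - (atanh(0.1) + 1.0)), 3 * se)
})

test_that("null calibration: edgewise z-difference t-test across seeds", {
  # fixed edge (1,2), no effect anywhere; 100 small datasets
  dz <- vapply(1:100, function(s) {
    cfg <- synth_config(n_rois = 3, n_timepoints = 60, voxels_per_roi = 1,
                        group_sizes = c(a = 6, b = 6),
                        planted_edges = cbind(1, 2),
                        effect_dz = c(a = 0, b = 0), voxel_noise_sd = 0,
                        ar1_coef = 0, drift_amplitude = 0, seed = 5000 + s)
    ds <- generate_dataset(cfg)
    z <- vapply(ds$subjects, function(sub)
      fisher_z(pearson_cor(sub$series[["1"]][, 1], sub$series[["2"]][, 1])),
      numeric(1))
    grp <- vapply(ds$subjects, `[[`, character(1), "group")
    mean(z[grp == "b"]) - mean(z[grp == "a"])
  }, numeric(1))
  expect_gt(t.test(dz)$p.value, 0.01)
})

test_that("correlation repair restores positive definiteness", {
  C <- matrix(c(1, 0.9, -0.9,
                0.9, 1, 0.9,
                -0.9, 0.9, 1), 3, 3)
  expect_lt(min(eigen(C, symmetric = TRUE)$values), 0)
  R <- forestconn:::repair_correlation(C)
  expect_gt(min(eigen(R, symmetric = TRUE)$values), 0)
  expect_equal(diag(R), rep(1, 3))
  # already-PD matrices pass through untouched
  P <- diag(3) * 0.8 + 0.2
  expect_identical(forestconn:::repair_correlation(P), P)
  # every group matrix sampled by the generator is PD after repair
  cfg <- synth_config(n_rois = 10, base_corr = 0.3,
                      planted_edges = cbind(c(1, 1, 2), c(2, 3, 3)),
                      effect_dz = c(saline = 0, LD = 1.5, HD = 3))
  for (g in c("saline", "LD", "HD")) {
    M <- forestconn:::group_correlation_matrix(cfg, g)
    expect_gt(min(eigen(M, symmetric = TRUE)$values), 0)
  }
})

test_that("dataset round-trips through the directory format", {
  ds <- toy_dataset(seed = 3, n_rois = 5, T = 25, V = 3, n_a = 2, n_b = 1)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_dataset(dir)
  expect_equal(length(back$subjects), 3)
  for (i in seq_along(ds$subjects)) {
    expect_equal(back$subjects[[i]]$subject_id, ds$subjects[[i]]$subject_id)
    expect_equal(back$subjects[[i]]$group, ds$subjects[[i]]$group)
    for (r in names(ds$subjects[[i]]$series))
      expect_equal(unname(back$subjects[[i]]$series[[r]]),
                   unname(ds$subjects[[i]]$series[[r]]), tolerance = 1e-12)
  }
  expect_equal(back$tr, ds$tr)
  expect_equal(back$atlas$name, ds$atlas$name)
})

test_that("dataset reader rejects broken directories", {
  ds <- toy_dataset(seed = 4, n_rois = 4, T = 20, V = 2, n_a = 2, n_b = 1)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  # manifest referencing a missing file
  victim <- list.files(file.path(dir, "series"), full.names = TRUE)[1]
  file.remove(victim)
  expect_error(read_dataset(dir), "missing file")

  # heterogeneous timepoint counts
  dir2 <- withr::local_tempdir()
  ds2 <- ds
  ds2$subjects[[2]]$series <- lapply(ds2$subjects[[2]]$series,
                                     function(m) m[1:10, , drop = FALSE])
  write_dataset(ds2, dir2)
  expect_error(read_dataset(dir2), "heterogeneous")

  expect_error(read_dataset(withr::local_tempdir()), "manifest")
})

test_that("ROI extraction returns labelled voxels in lexicographic order", {
  dims <- c(4, 4, 2)
  Tn <- 10
  img <- array(seq_len(prod(dims) * Tn), c(dims, Tn))
  lab <- array(0L, dims)
  lab[2, 1, 1] <- 1L; lab[1, 3, 2] <- 1L; lab[4, 4, 1] <- 1L
  lab[3, 3, 1] <- 2L
  rec <- extract_roi_series(img, lab, subject_id = "s1", group = "g")
  m <- rec$series[["1"]]
  expect_equal(dim(m), c(10L, 3L))
  # lexicographic (x,y,z): (1,3,2), (2,1,1), (4,4,1)
  expected <- sapply(list(c(1, 3, 2), c(2, 1, 1), c(4, 4, 1)), function(v)
    img[v[1], v[2], v[3], ])
  expect_equal(unname(m), unname(expected))
  # ROI mean equals brute-force voxel mean at every timepoint
  expect_equal(rowMeans(m), colMeans(rbind(img[1, 3, 2, ], img[2, 1, 1, ],
                                           img[4, 4, 1, ])))
  expect_equal(dim(rec$series[["2"]]), c(10L, 1L))

  expect_error(extract_roi_series(img, array(0L, dims)), "no nonzero")
  expect_error(extract_roi_series(img, array(0L, c(3, 4, 2))), "same spatial")
  expect_error(extract_roi_series(img, lab, labels = c(1, 5)), "absent")
})
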
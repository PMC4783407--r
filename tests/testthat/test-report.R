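test_that("summaries count outcomes and report accuracy", {
  preds <- data.frame(outcome = c("correct", "false", "unclassified",
                                  "correct", "correct"))
  s <- summarize_comparison(preds, "demo")
  expect_equal(unlist(s[, c("correct", "false", "unclassified", "k")]),
               c(correct = 3, false = 1, unclassified = 1, k = 5))
  expect_equal(s$accuracy, 3 / 5)
  s2 <- summarize_comparison(data.frame(outcome = rep("correct", 4)))
  expect_equal(s2$accuracy, 1.0)
  expect_equal(s2$correct + s2$false + s2$unclassified, s2$k)
  expect_error(summarize_comparison(NULL), "empty")
})

test_that("region importance aggregates by rule and thresholds display", {
  atlas <- make_atlas_labels(10)
  mk_subset <- function(df) {
    df$name <- if (nrow(df)) paste0(df$region_i, "|", df$region_j)
               else character(0)
    class(df) <- c("feature_subset", "data.frame")
    df
  }
  one <- mk_subset(data.frame(feature_id = 1L, region_i = 2L, region_j = 5L,
                              importance = 3.0))
  tab <- region_importance_table(list(cmp = one), atlas)
  expect_equal(tab$score[tab$region_id == 2], 3.0)
  expect_equal(tab$score[tab$region_id == 5], 3.0)

  two <- mk_subset(data.frame(feature_id = c(1L, 2L),
                              region_i = c(2L, 2L), region_j = c(5L, 7L),
                              importance = c(2.0, 4.0)))
  expect_equal(region_importance_table(list(x = two), atlas,
                                       rule = "max")$score[1], 4.0)
  expect_equal(region_importance_table(list(x = two), atlas,
                                       rule = "sum")$score[1], 6.0)
  expect_equal(region_importance_table(list(x = two), atlas,
                                       rule = "mean")$score[1], 3.0)
  # sub-threshold scores are rendered "<2"
  low <- mk_subset(data.frame(feature_id = 1L, region_i = 1L, region_j = 3L,
                              importance = 1.2))
  expect_true(all(region_importance_table(list(x = low),
                                          atlas)$display == "<2"))
  # empty subset -> empty table with headers
  empty <- mk_subset(data.frame(feature_id = integer(0),
                                region_i = integer(0),
                                region_j = integer(0),
                                importance = numeric(0)))
  et <- region_importance_table(list(x = empty), atlas)
  expect_equal(nrow(et), 0)
  expect_true(all(c("comparison", "name", "side", "score") %in% names(et)))
  # unresolvable annotation -> failure
  orphan <- mk_subset(data.frame(feature_id = 1L, region_i = 2L,
                                 region_j = 99L, importance = 3))
  expect_error(region_importance_table(list(x = orphan), atlas), "absent")
})

test_that("config loading validates before any compute", {
  expect_error(load_config(list(data = list(source = "nope"))),
               class = "config_error")
  expect_error(load_config(list(data = list(source = "directory"))),
               class = "config_error")
  expect_error(load_config(
    list(data = list(synthesis = list(group_sizes = c(5, 5))))),
    class = "config_error")
  expect_error(load_config("/no/such/file.yaml"), class = "config_error")
  cfg <- load_config(list(seed = 5))
  expect_equal(cfg$seed, 5)
  expect_equal(cfg$selection$k, 10)
})

test_that("run_pipeline emits three pairwise comparisons plus dose contrast", {
  out <- withr::local_tempdir()
  cfg <- list(
    output_dir = out, seed = 7,
    data = list(synthesis = list(
      n_rois = 10, n_timepoints = 80, voxels_per_roi = 4,
      group_sizes = list(saline = 5, LD = 4, HD = 4),
      planted_edges = list(c(1, 2), c(3, 4)),
      effect_dz = list(saline = 0, LD = 1.2, HD = 2.4))),
    classification = list(n_trees = 80),
    selection = list(k = 4, control_group = "saline"))
  res <- suppressMessages(run_pipeline(cfg))
  smry <- res$summary
  expect_setequal(unique(smry$comparison),
                  c("HD_vs_LD", "HD_vs_saline", "LD_vs_saline"))
  expect_true(all(smry$correct + smry$false + smry$unclassified == smry$k))
  expect_true(all(table(smry$comparison) >= 2)) # full + top-k per pair
  expect_true(file.exists(file.path(out, "summary.tsv")))
  expect_true(file.exists(file.path(out, "region_importance.tsv")))

  # provenance header present
  head2 <- readLines(file.path(out, "summary.tsv"), n = 3)
  expect_true(any(grepl("config_hash=", head2)))
  expect_true(any(grepl("seed=7", head2)))

  # rerun into a different directory: numerically identical tables and the
  # same provenance hash (hash covers the scientific config only)
  out2 <- withr::local_tempdir()
  cfg2 <- cfg; cfg2$output_dir <- out2
  suppressMessages(run_pipeline(cfg2))
  expect_identical(readLines(file.path(out, "summary.tsv")),
                   readLines(file.path(out2, "summary.tsv")))
})

test_that("cli dispatches subcommands and reports exit codes", {
  expect_equal(suppressMessages(forestconn_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(forestconn_cli(character(0))), 2L)
  expect_equal(suppressMessages(forestconn_cli(c("run", "--bogus", "x"))), 2L)

  out <- file.path(withr::local_tempdir(), "sim")
  cfgfile <- file.path(withr::local_tempdir(), "cfg.yaml")
  yaml::write_yaml(list(
    seed = 3,
    data = list(synthesis = list(
      n_rois = 4, n_timepoints = 20, voxels_per_roi = 2,
      group_sizes = list(a = 2, b = 2),
      planted_edges = list(c(1, 2)),
      effect_dz = list(a = 0, b = 1)))), cfgfile)
  code <- suppressMessages(forestconn_cli(c("simulate", "--config", cfgfile,
                                            "--out", out)))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  ds <- read_dataset(out)
  expect_equal(length(ds$subjects), 4)
})
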
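#' Summarize leave-one-out predictions
#'
#' @param predictions Prediction table (one row per subject) as produced by
#'   [loo_classify()] / [nested_loo_with_selection()].
#' @param comparison Optional comparison label carried into the summary.
#' @return One-row `data.frame`: `comparison`, `correct`, `false`,
#'   `unclassified`, `k` (total subjects), `accuracy` (= correct / k).
#' @export
summarize_comparison <- function(predictions, comparison = NA_character_) {
  if (is.null(predictions) || nrow(predictions) == 0)
    stop("empty prediction list")
  cnt <- table(factor(predictions$outcome,
                      levels = c("correct", "false", "unclassified")))
  k <- nrow(predictions)
  data.frame(comparison = comparison,
             correct = as.integer(cnt[["correct"]]),
             false = as.integer(cnt[["false"]]),
             unclassified = as.integer(cnt[["unclassified"]]),
             k = k,
             accuracy = as.integer(cnt[["correct"]]) / k)
}

#' Map selected features back to anatomical regions
#'
#' Aggregates the importance of every selected feature touching a region into
#' a per-region score, per comparison. Scores below the display threshold are
#' rendered as `"<threshold"`, mirroring the usual presentation of
#' region-importance tables.
#'
#' @param subsets Named list of `feature_subset`s (one per comparison), each
#'   carrying `region_i`, `region_j` and `importance`.
#' @param atlas Atlas table ([make_atlas_labels()]).
#' @param rule Aggregation over the features touching a region: `"max"`
#'   (default), `"sum"` or `"mean"`.
#' @param threshold Display threshold (default 2.0); purely presentational.
#' @return `data.frame` with `comparison`, `region_id`, `name`, `side`,
#'   `score`, `display`.
#' @export
region_importance_table <- function(subsets, atlas, rule = c("max", "sum",
                                                             "mean"),
                                    threshold = 2.0) {
  rule <- match.arg(rule)
  if (inherits(subsets, "data.frame")) subsets <- list(subsets)
  if (is.null(names(subsets)) || any(names(subsets) == ""))
    names(subsets) <- paste0("comparison_", seq_along(subsets))
  agg <- switch(rule, max = max, sum = sum, mean = mean)

  rows <- lapply(names(subsets), function(cmp) {
    s <- subsets[[cmp]]
    if (nrow(s) == 0)
      return(data.frame(comparison = character(0), region_id = integer(0),
                        name = character(0), side = character(0),
                        score = numeric(0), display = character(0)))
    touched <- unique(c(s$region_i, s$region_j))
    bad <- setdiff(touched, atlas$region_id)
    if (length(bad) > 0)
      stop("feature annotation references region(s) absent from atlas: ",
           paste(bad, collapse = ", "))
    touched <- sort(touched)
    score <- vapply(touched, function(r)
      agg(s$importance[s$region_i == r | s$region_j == r]), numeric(1))
    a <- atlas[match(touched, atlas$region_id), ]
    data.frame(comparison = cmp, region_id = touched, name = a$name,
               side = a$side, score = score,
               display = ifelse(score < threshold,
                                paste0("<", format(threshold)),
                                formatC(score, digits = 3, format = "g")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Restrict a feature matrix to a subset of groups
#'
#' @param fm A `feature_matrix`.
#' @param groups Group labels to keep (e.g. the two arms of a pairwise
#'   comparison); unused factor levels are dropped.
#' @return The restricted `feature_matrix`.
#' @export
subset_subjects <- function(fm, groups) {
  keep <- fm$groups %in% groups
  fm$x <- fm$x[keep, , drop = FALSE]
  fm$groups <- droplevels(fm$groups[keep])
  fm
}

config_error <- function(msg) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

default_config <- function() {
  list(
    output_dir = "forestconn_results",
    seed = 1L,
    data = list(source = "synthetic", path = NULL, synthesis = list()),
    reduction = list(method = "pca", n_components = 1, n_neighbors = 10,
                     perplexity = 15, highpass_window = "auto",
                     standardize = TRUE),
    classification = list(n_trees = 500, min_leaf = 1,
                          band = c(0.45, 0.55)),
    selection = list(k = 10, consensus_threshold = 0.5,
                     exclusive_mode = "pair", control_group = NULL),
    report = list(aggregate = "max", display_threshold = 2.0))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param config A YAML file path or a nested list; missing entries fall back
#'   to the defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error(paste("config file not found:",
                                                 config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or YAML path")
  cfg <- merge_config(default_config(), config)
  if (!cfg$data$source %in% c("synthetic", "directory"))
    config_error("data.source must be 'synthetic' or 'directory'")
  if (cfg$data$source == "directory" && is.null(cfg$data$path))
    config_error("data.source = directory requires data.path")
  if (cfg$data$source == "synthetic") {
    gs <- cfg$data$synthesis$group_sizes
    if (!is.null(gs) && (is.null(names(gs)) || any(names(gs) == "")))
      config_error("synthesis.group_sizes must map group labels to counts")
  }
  if (!cfg$reduction$method %in% c("pca", "isomap", "tsne", "lle"))
    config_error("unknown reduction method: ")
  if (length(cfg$classification$band) != 2)
    config_error("classification.band must have two entries")
  cfg
}

pipeline_dataset <- function(cfg) {
  if (cfg$data$source == "directory") return(read_dataset(cfg$data$path))
  syn <- cfg$data$synthesis
  if (!is.null(syn$group_sizes)) syn$group_sizes <- unlist(syn$group_sizes)
  if (!is.null(syn$effect_dz)) syn$effect_dz <- unlist(syn$effect_dz)
  if (!is.null(syn$planted_edges))
    syn$planted_edges <- do.call(rbind, lapply(syn$planted_edges, unlist))
  if (is.null(syn$seed)) syn$seed <- cfg$seed
  generate_dataset(do.call(synth_config, syn))
}

write_tsv_provenance <- function(df, path, cfg_hash, seed) {
  header <- c(paste0("# forestconn ",
                     as.character(utils::packageVersion("forestconn"))),
              paste0("# config_hash=", cfg_hash),
              paste0("# seed=", seed))
  writeLines(header, path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the whole pipeline from a configuration
#'
#' Synthesize (or load) the dataset, reduce each ROI, build connectivity
#' feature matrices, classify every pair of groups by leave-one-out random
#' forest (full feature set and nested top-k selection) and, when three
#' groups with a designated control are present, run the dose-versus-dose
#' contrast on the mutually-exclusive feature set of the two control
#' comparisons (on the published procedure, that selection uses all subjects
#' of the two control comparisons and is therefore not nested in the dose
#' contrast's own cross-validation; see the vignette). All tables are written
#' as TSV with a provenance header (package version, config hash, master
#' seed); re-running an identical configuration reproduces them byte for
#' byte.
#'
#' @param config YAML path or nested configuration list (see [load_config()]).
#' @return Invisibly, a list with the dataset, per-comparison results, the
#'   region importance table and the output directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  # hash the scientific configuration only, so the same analysis written to
  # a different directory carries the same provenance hash
  cfg_hash <- digest::digest(cfg[setdiff(names(cfg), "output_dir")])
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$output_dir, "pipeline.log")
  log_msg <- function(...) {
    txt <- paste0(...)
    message("[forestconn] ", txt)
    cat(txt, "\n", file = logf, append = TRUE)
  }
  cat("", file = logf)
  yaml::write_yaml(cfg, file.path(cfg$output_dir, "config.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("stage_error", "error", "condition"),
                     list(message = paste0("stage '", name, "': ",
                                           conditionMessage(e)),
                          call = NULL)))
    })
  }

  log_msg("stage: data (source=", cfg$data$source, ")")
  dataset <- stage("data", pipeline_dataset(cfg))
  groups <- levels(factor(vapply(dataset$subjects, `[[`, character(1),
                                 "group")))
  if (length(groups) < 2) config_error("dataset has fewer than 2 groups")

  log_msg("stage: reduction (", cfg$reduction$method, ") + connectivity")
  rp <- reduction_params(cfg$reduction$method, cfg$reduction$n_components,
                         cfg$reduction$n_neighbors, cfg$reduction$perplexity,
                         seed = cfg$seed)
  hw <- cfg$reduction$highpass_window
  fm <- stage("reduction", dataset_feature_matrix(dataset, rp,
                                                  highpass_window = hw,
                                                  standardize =
                                                    cfg$reduction$standardize))

  fp <- forest_params(cfg$classification$n_trees, cfg$classification$min_leaf,
                      seed = cfg$seed)
  band <- cfg$classification$band
  k <- cfg$selection$k

  pairs_of_groups <- utils::combn(groups, 2, simplify = FALSE)
  results <- list(); summaries <- list(); consensus <- list()
  for (pg in pairs_of_groups) {
    cmp <- paste0(pg[1], "_vs_", pg[2])
    log_msg("stage: classification ", cmp)
    fmc <- subset_subjects(fm, pg)
    full <- stage(cmp, loo_classify(fmc, fp, band))
    nested <- stage(cmp, nested_loo_with_selection(fmc, k, fp, band,
                                                   cfg$selection$consensus_threshold))
    results[[cmp]] <- list(full = full, nested = nested)
    consensus[[cmp]] <- nested$consensus
    summaries[[length(summaries) + 1L]] <-
      cbind(summarize_comparison(full$predictions, cmp),
            feature_set = "full")
    summaries[[length(summaries) + 1L]] <-
      cbind(summarize_comparison(nested$predictions, cmp),
            feature_set = paste0("top", k))
    write_tsv_provenance(full$predictions,
                         file.path(cfg$output_dir,
                                   paste0("predictions_full_", cmp, ".tsv")),
                         cfg_hash, cfg$seed)
    write_tsv_provenance(nested$predictions,
                         file.path(cfg$output_dir,
                                   paste0("predictions_top", k, "_", cmp,
                                          ".tsv")),
                         cfg_hash, cfg$seed)
    write_tsv_provenance(nested$consensus,
                         file.path(cfg$output_dir,
                                   paste0("consensus_", cmp, ".tsv")),
                         cfg_hash, cfg$seed)
  }

  # dose-vs-dose contrast on mutually-exclusive features of the two
  # control comparisons
  control <- cfg$selection$control_group %||%
    (if (length(groups) == 3) groups[groups %in% c("saline", "control",
                                                   "vehicle")][1] else NA)
  if (length(groups) == 3 && !is.na(control) && control %in% groups) {
    doses <- setdiff(groups, control)
    cmp_a <- paste0(min(control, doses[1]), "_vs_", max(control, doses[1]))
    cmp_b <- paste0(min(control, doses[2]), "_vs_", max(control, doses[2]))
    dose_cmp <- paste0(doses[1], "_vs_", doses[2], "_exclusive")
    log_msg("stage: dose contrast ", dose_cmp)
    excl <- mutually_exclusive_features(consensus[[cmp_a]], consensus[[cmp_b]],
                                        mode = cfg$selection$exclusive_mode)
    if (nrow(excl) > 0) {
      fmd <- subset_subjects(fm, doses)
      fmd <- subset_features(fmd, excl$feature_id)
      dose <- stage(dose_cmp, loo_classify(fmd, fp, band))
      results[[dose_cmp]] <- list(full = dose, features = excl)
      summaries[[length(summaries) + 1L]] <-
        cbind(summarize_comparison(dose$predictions,
                                   paste0(doses[1], "_vs_", doses[2])),
              feature_set = "exclusive")
      write_tsv_provenance(dose$predictions,
                           file.path(cfg$output_dir,
                                     paste0("predictions_", dose_cmp, ".tsv")),
                           cfg_hash, cfg$seed)
      write_tsv_provenance(excl,
                           file.path(cfg$output_dir,
                                     paste0("features_", dose_cmp, ".tsv")),
                           cfg_hash, cfg$seed)
    } else {
      log_msg("dose contrast skipped: empty exclusive feature set")
    }
  }

  summary_tab <- do.call(rbind, summaries)
  write_tsv_provenance(summary_tab, file.path(cfg$output_dir, "summary.tsv"),
                       cfg_hash, cfg$seed)

  nonempty <- Filter(function(s) nrow(s) > 0, consensus)
  region_tab <- if (length(nonempty) > 0)
    region_importance_table(nonempty, dataset$atlas,
                            rule = cfg$report$aggregate,
                            threshold = cfg$report$display_threshold)
  else NULL
  if (!is.null(region_tab))
    write_tsv_provenance(region_tab,
                         file.path(cfg$output_dir, "region_importance.tsv"),
                         cfg_hash, cfg$seed)

  log_msg("done: ", cfg$output_dir)
  invisible(list(dataset = dataset, feature_matrix = fm, results = results,
                 summary = summary_tab, region_importance = region_tab,
                 output_dir = cfg$output_dir))
}
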
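#' Select the top-k most important features
#'
#' @param ranking An `importance_ranking` (see [permutation_importance()]).
#' @param k Number of features to keep (>= 1); `k >= p` keeps all features.
#' @return Object of class `feature_subset`: the selected rows of the
#'   ranking, ordered by rank (ties already broken by ascending feature
#'   index).
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(is.data.frame(ranking),
            all(c("feature_id", "importance", "rank") %in% names(ranking)))
  if (k < 1) stop("k must be >= 1")
  k <- min(k, nrow(ranking))
  out <- ranking[order(ranking$rank), , drop = FALSE][seq_len(k), ,
                                                      drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_subset", "data.frame")
  out
}

#' Nested leave-one-out with per-fold feature selection
#'
#' The full re-evaluation procedure: inside every fold, a forest is fitted on
#' the N-1 training subjects, permutation importance is computed on the
#' training subjects only, the top-k features are selected, the forest is
#' refitted on the reduced columns, and only then is the held-out subject
#' scored. The held-out row therefore never influences selection. The
#' consensus subset collects the features selected in at least
#' `consensus_threshold` of the folds.
#'
#' @inheritParams loo_classify
#' @param k Features kept per fold (default 10). `k >= p` makes selection a
#'   no-op and reproduces [loo_classify()] exactly.
#' @param consensus_threshold Minimum fraction of folds a feature must be
#'   selected in to enter the consensus subset (default 0.5).
#' @return List with `predictions`, `summary`, `fold_subsets` (list of
#'   `feature_subset`, one per fold) and `consensus` (a `feature_subset` with
#'   `fold_frequency` and fold-averaged importance).
#' @export
nested_loo_with_selection <- function(fm, k = 10, params = forest_params(),
                                      band = c(0.45, 0.55),
                                      consensus_threshold = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x; y <- droplevels(fm$groups)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 subjects")
  if (nlevels(y) != 2) stop("leave-one-out classification expects 2 groups")

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed)
  fold_seeds <- sample.int(2^30, n)

  folds <- lapply(seq_len(n), function(i) {
    fp <- params; fp$seed <- fold_seeds[i]
    loo_fold(x, y, i, fp, band, k = k, pairs = fm$pairs)
  })
  predictions <- do.call(rbind, lapply(folds, `[[`, "prediction"))
  fold_subsets <- lapply(folds, `[[`, "subset")

  consensus <- consensus_subset(fold_subsets, fm$pairs, n,
                                consensus_threshold)
  list(predictions = predictions,
       summary = summarize_comparison(predictions),
       fold_subsets = fold_subsets,
       consensus = consensus)
}

consensus_subset <- function(fold_subsets, pairs, n_folds, threshold = 0.5) {
  real <- Filter(Negate(is.null), fold_subsets)
  if (length(real) == 0) { # selection was a no-op (k >= p)
    out <- pairs[0, , drop = FALSE]
    out$importance <- numeric(0); out$fold_frequency <- numeric(0)
    class(out) <- c("feature_subset", "data.frame")
    return(out)
  }
  ids <- unlist(lapply(real, `[[`, "feature_id"))
  imps <- unlist(lapply(real, `[[`, "importance"))
  freq <- table(ids) / n_folds
  keep <- as.integer(names(freq)[freq >= threshold])
  keep <- sort(keep)
  out <- pairs[match(keep, pairs$feature_id), , drop = FALSE]
  out$importance <- vapply(keep, function(id) mean(imps[ids == id]),
                           numeric(1))
  out$fold_frequency <- as.numeric(freq[as.character(keep)])
  out <- out[order(-out$fold_frequency, -out$importance, out$feature_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_subset", "data.frame")
  out
}

#' Sweep the number of selected features
#'
#' Runs [nested_loo_with_selection()] once per requested `k` under a shared
#' master seed and tabulates the outcome counts, reproducing the robustness
#' check that accuracy degrades as weak features are added back in.
#'
#' @inheritParams nested_loo_with_selection
#' @param ks Integer vector of k values, each `<= p`.
#' @return `data.frame` with columns `k`, `correct`, `false`, `unclassified`,
#'   `accuracy`.
#' @export
k_sweep <- function(fm, ks, params = forest_params(), band = c(0.45, 0.55)) {
  if (length(ks) == 0) stop("ks must be non-empty")
  if (any(ks < 1 | ks > ncol(fm$x))) stop("each k must be in 1..p")
  rows <- lapply(ks, function(k) {
    res <- nested_loo_with_selection(fm, k = k, params = params, band = band)
    cbind(data.frame(k = k),
          res$summary[, c("correct", "false", "unclassified", "accuracy")])
  })
  do.call(rbind, rows)
}

#' Mutually-exclusive features between two comparisons
#'
#' Implements the dose-contrast selection: given the important-feature
#' subsets of two control-versus-dose comparisons, keep the features that
#' appear in exactly one of them — the rationale being that a feature present
#' in only one comparison reflects the dose rather than shared drug/control
#' effects. The default operates on ROI pairs (the symmetric difference of
#' the two feature-id sets); `mode = "region"` instead keeps the features
#' (from either subset) touching an anatomical region that occurs in only one
#' comparison's region set.
#'
#' @param subset_a,subset_b `feature_subset`s annotated against the same
#'   atlas/pair index.
#' @param mode `"pair"` (default) or `"region"`.
#' @return A `feature_subset` (possibly empty, with a warning; downstream
#'   classification refuses a 0-feature matrix).
#' @export
mutually_exclusive_features <- function(subset_a, subset_b,
                                        mode = c("pair", "region")) {
  mode <- match.arg(mode)
  stopifnot(inherits(subset_a, "data.frame"), inherits(subset_b, "data.frame"))
  both <- rbind(subset_a[, intersect(names(subset_a), names(subset_b)),
                         drop = FALSE],
                subset_b[, intersect(names(subset_a), names(subset_b)),
                         drop = FALSE])

  if (mode == "pair") {
    excl <- setdiff(union(subset_a$feature_id, subset_b$feature_id),
                    intersect(subset_a$feature_id, subset_b$feature_id))
    out <- both[match(sort(excl), both$feature_id), , drop = FALSE]
  } else {
    regions <- function(s) unique(c(s$region_i, s$region_j))
    ra <- regions(subset_a); rb <- regions(subset_b)
    excl_regions <- setdiff(union(ra, rb), intersect(ra, rb))
    ids <- unique(both$feature_id[both$region_i %in% excl_regions |
                                    both$region_j %in% excl_regions])
    out <- both[match(sort(ids), both$feature_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("feature_subset", "data.frame")
  if (nrow(out) == 0)
    warning("mutually-exclusive selection produced an empty feature set")
  out
}
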
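#' Random-forest parameters
#'
#' @param n_trees Number of trees (>= 10); default 500.
#' @param min_leaf Minimum leaf size; default 1 (grow until pure).
#' @param mtry Features tried per split; default `floor(sqrt(p))`, min 1,
#'   resolved at fit time when `NULL`.
#' @param seed Integer seed; bootstrap draws, split sampling and permutations
#'   all flow from it.
#' @return Object of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500, min_leaf = 1, mtry = NULL,
                          seed = 1L) {
  if (n_trees < 10) stop("n_trees must be >= 10")
  if (min_leaf < 1) stop("min_leaf must be >= 1")
  structure(list(n_trees = as.integer(n_trees), min_leaf = as.integer(min_leaf),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 seed = as.integer(seed)),
            class = "forest_params")
}

resolve_xy <- function(x, y) {
  if (inherits(x, "feature_matrix")) {
    y <- x$groups
    x <- x$x
  }
  if (!is.factor(y)) y <- factor(y)
  list(x = as.matrix(x), y = y)
}

#' Fit a random forest
#'
#' Bagged CART trees with per-node random feature subsampling (Gini
#' criterion). The fitted object exposes the per-tree structure and the
#' bootstrap in-bag counts, which the out-of-bag error and the per-tree
#' permutation importance are computed from. Deterministic given
#' `params$seed`.
#'
#' @param x Feature matrix (subjects x features) or a `feature_matrix`.
#' @param y Group factor (ignored when `x` is a `feature_matrix`).
#' @param params [forest_params()].
#' @return Object of class `rf_forest`: list with `trees`, `inbag`
#'   (subjects x trees bootstrap counts), `classes`, `params`, `n_features`.
#' @export
fit_forest <- function(x, y = NULL, params = forest_params()) {
  d <- resolve_xy(x, y)
  if (nlevels(droplevels(d$y)) < 2)
    stop("training set contains a single class")
  if (anyNA(d$x)) stop("missing values in feature matrix")

  p <- ncol(d$x)
  mtry <- params$mtry %||% max(1L, floor(sqrt(p)))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed)
  fit <- rf_fit_cpp(d$x, as.integer(d$y) - 1L, nlevels(d$y), params$n_trees,
                    mtry, params$min_leaf)
  structure(list(trees = fit$trees, inbag = fit$inbag,
                 classes = levels(d$y), params = params, n_features = p),
            class = "rf_forest")
}

#' @export
print.rf_forest <- function(x, ...) {
  cat("<rf_forest> ", length(x$trees), " trees, ", x$n_features,
      " features, classes: ", paste(x$classes, collapse = " vs "), "\n",
      sep = "")
  invisible(x)
}

#' Per-class vote fractions of a fitted forest
#'
#' @param forest An `rf_forest`.
#' @param newx Matrix of rows to score (same feature columns as training).
#' @return Matrix (rows of `newx`) x classes of vote fractions summing to 1.
#' @export
predict_votes <- function(forest, newx) {
  newx <- as.matrix(newx)
  if (ncol(newx) != forest$n_features)
    stop("feature count mismatch: forest has ", forest$n_features)
  votes <- rf_predict_cpp(forest$trees, newx) # rows x trees, 0-based class
  out <- vapply(seq_along(forest$classes) - 1L,
                function(c) rowMeans(votes == c),
                numeric(nrow(newx)))
  out <- matrix(out, nrow = nrow(newx),
                dimnames = list(rownames(newx), forest$classes))
  out
}

#' Out-of-bag error of a fitted forest
#'
#' Each training subject is predicted only by the trees in whose bootstrap
#' sample it did not appear; the returned value is the proportion of
#' misclassified subjects. Subjects that were in-bag for every tree (possible
#' at small `n_trees`) are excluded with a warning.
#'
#' @param forest An `rf_forest` fitted on `x`, `y`.
#' @param x,y The training data the forest was fitted on.
#' @return Proportion misclassified, in \[0, 1\].
#' @export
oob_error <- function(forest, x, y = NULL) {
  d <- resolve_xy(x, y)
  votes <- rf_predict_cpp(forest$trees, d$x)
  oob <- forest$inbag == 0
  n_oob <- rowSums(oob)
  if (any(n_oob == 0))
    warning(sum(n_oob == 0), " subject(s) in-bag for all trees; excluded")
  keep <- which(n_oob > 0)
  K <- length(forest$classes)
  pred <- vapply(keep, function(i) {
    v <- tabulate(votes[i, oob[i, ]] + 1L, nbins = K)
    which.max(v) # ties -> lowest class index
  }, integer(1))
  mean(pred != as.integer(d$y)[keep])
}

#' Out-of-bag permutation importance
#'
#' For each tree and each feature the tree uses, the feature's values are
#' randomly permuted among the tree's out-of-bag subjects and the increase of
#' that tree's OOB error is recorded; a feature's importance is the mean
#' increase over all trees (features a tree ignores contribute exactly zero
#' for it, so constant features score exactly 0). Ranks break ties by
#' ascending feature index.
#'
#' @param forest An `rf_forest`.
#' @param x,y Training data.
#' @param seed Seed for the permutations (default: forest seed + 1).
#' @param pairs Optional feature annotation table (e.g. `fm$pairs`) carried
#'   into the ranking.
#' @return Object of class `importance_ranking`: `data.frame` with
#'   `feature_id`, `importance`, `rank` and, when available, ROI-pair columns.
#' @export
permutation_importance <- function(forest, x, y = NULL, seed = NULL,
                                   pairs = NULL) {
  d <- resolve_xy(x, y)
  if (inherits(x, "feature_matrix") && is.null(pairs)) pairs <- x$pairs
  seed <- seed %||% (forest$params$seed + 1L)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  imp <- rf_importance_cpp(forest$trees, forest$inbag, d$x,
                           as.integer(d$y) - 1L)
  make_importance_ranking(imp, pairs)
}

# Rank a raw importance vector (ties broken by ascending feature index) and
# attach optional ROI-pair annotation.
make_importance_ranking <- function(imp, pairs = NULL) {
  p <- length(imp)
  rk <- integer(p)
  rk[order(-imp, seq_len(p))] <- seq_len(p)
  out <- data.frame(feature_id = seq_len(p), importance = imp, rank = rk)
  if (!is.null(pairs)) {
    stopifnot(nrow(pairs) == p)
    out <- cbind(out, pairs[, setdiff(names(pairs), "feature_id"),
                            drop = FALSE])
  }
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Outcome of a vote fraction under the unclassified band
#'
#' A subject whose vote fraction for the true class falls inside the band
#' (boundaries inclusive) is "unclassified"; above the band it is "correct",
#' below it "false".
#'
#' @param p_true Vote fraction(s) for the true class.
#' @param band Length-2 numeric band, default `c(0.45, 0.55)`.
#' @return Character vector in `{correct, false, unclassified}`.
#' @export
band_outcome <- function(p_true, band = c(0.45, 0.55)) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  ifelse(p_true > band[2], "correct",
         ifelse(p_true < band[1], "false", "unclassified"))
}

# One leave-one-out fold: fit on all subjects except `holdout`, optionally
# run permutation importance + top-k selection + refit on the training rows
# only, then score the held-out subject. The held-out row is touched only at
# the final predict_votes call (no leakage).
loo_fold <- function(x, y, holdout, params, band = c(0.45, 0.55), k = NULL,
                     pairs = NULL, return_forest = FALSE) {
  train_x <- x[-holdout, , drop = FALSE]
  train_y <- y[-holdout]
  fp <- params
  forest <- fit_forest(train_x, train_y, fp)

  subset <- NULL
  cols <- seq_len(ncol(x))
  if (!is.null(k) && k < ncol(x)) {
    imp <- permutation_importance(forest, train_x, train_y,
                                  seed = fp$seed + 1L, pairs = pairs)
    subset <- select_top_k(imp, k)
    cols <- subset$feature_id
    train_x <- train_x[, cols, drop = FALSE]
    forest <- fit_forest(train_x, train_y, fp)
  }

  test_x <- x[holdout, cols, drop = FALSE]
  pv <- predict_votes(forest, test_x)
  true_cls <- as.character(y[holdout])
  p_true <- pv[1, true_cls]
  pred_cls <- colnames(pv)[which.max(pv[1, ])]
  out <- list(
    prediction = data.frame(
      subject_id = rownames(x)[holdout] %||% as.character(holdout),
      true_group = true_cls, predicted_group = pred_cls,
      p_true = unname(p_true), outcome = band_outcome(p_true, band)),
    subset = subset)
  if (return_forest) {
    out$forest <- forest
    out$train_votes <- predict_votes(forest, train_x)
  }
  out
}

#' Leave-one-out random-forest classification
#'
#' Fits N independent forests, each on N-1 subjects, and scores the held-out
#' subject by the fraction of trees voting for its true group; outcomes are
#' assigned by the \[0.45, 0.55\] unclassified band. Per-fold seeds are drawn
#' once from `params$seed`, so the whole run is reproducible.
#'
#' @param fm A two-group `feature_matrix` with >= 4 subjects.
#' @param params [forest_params()].
#' @param band Unclassified band.
#' @return List with `predictions` (one row per subject: `subject_id`,
#'   `true_group`, `predicted_group`, `p_true`, `outcome`) and `summary`
#'   (see [summarize_comparison()]).
#' @export
loo_classify <- function(fm, params = forest_params(), band = c(0.45, 0.55)) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x; y <- droplevels(fm$groups)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 subjects")
  if (nlevels(y) != 2) stop("leave-one-out classification expects 2 groups")

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed)
  fold_seeds <- sample.int(2^30, n)

  preds <- lapply(seq_len(n), function(i) {
    fp <- params; fp$seed <- fold_seeds[i]
    loo_fold(x, y, i, fp, band)$prediction
  })
  predictions <- do.call(rbind, preds)
  list(predictions = predictions,
       summary = summarize_comparison(predictions))
}
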
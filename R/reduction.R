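#' Reduction parameters
#'
#' Controls how each ROI's multi-voxel time series (T timepoints x V voxels)
#' is embedded into `n_components` dimensions, treating timepoints as samples
#' and voxels as features. Method-specific settings are ignored by the other
#' methods.
#'
#' @param method One of `"pca"`, `"isomap"`, `"tsne"`, `"lle"`.
#' @param n_components Embedding dimension d (default 1, so downstream ROI
#'   correlation is an ordinary scalar-series correlation).
#' @param n_neighbors k-nearest-neighbor count for isomap/LLE.
#' @param perplexity t-SNE perplexity (clamped to (T-1)/3 when T is small).
#' @param seed Seed for the stochastic methods (t-SNE initialization).
#' @return Object of class `reduction_params`.
#' @export
reduction_params <- function(method = c("pca", "isomap", "tsne", "lle"),
                             n_components = 1, n_neighbors = 10,
                             perplexity = 15, seed = 1L) {
  method <- match.arg(method)
  if (n_components < 1) stop("n_components must be >= 1")
  structure(list(method = method, n_components = as.integer(n_components),
                 n_neighbors = as.integer(n_neighbors),
                 perplexity = perplexity, seed = as.integer(seed)),
            class = "reduction_params")
}

#' Reduce one ROI's voxel time series to a low-dimensional time course
#'
#' Embeds the T x V matrix (timepoints as samples, voxels as features) with
#' the chosen manifold / linear method. Each output component is sign-fixed
#' to correlate non-negatively with the ROI's mean voxel time course
#' (embeddings are sign-indeterminate, and the downstream correlation
#' features are sign-sensitive) and z-scored. A single-voxel ROI needs no
#' embedding: every method returns its z-scored series.
#'
#' @param series Numeric T x V matrix (or length-T vector).
#' @param params A [reduction_params()].
#' @param roi_id Label used in error messages.
#' @return T x d numeric matrix.
#' @export
reduce_roi <- function(series, params = reduction_params(), roi_id = "?") {
  x <- as.matrix(series)
  Tn <- nrow(x); V <- ncol(x); d <- params$n_components
  if (anyNA(x)) stop("ROI ", roi_id, ": missing values")
  if (Tn <= d) stop("ROI ", roi_id, ": need more timepoints than components")
  if (V < d) stop("ROI ", roi_id, ": fewer voxels than components")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("ROI ", roi_id, ": constant (degenerate) input")

  if (V == 1) {
    y <- matrix((x - mean(x)) / stats::sd(x), ncol = 1)
  } else {
    y <- switch(params$method,
      pca = stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(d),
                                                              drop = FALSE],
      isomap = embed_isomap(x, d, params$n_neighbors),
      tsne = embed_tsne(x, d, params$perplexity, params$seed),
      lle = embed_lle(x, d, params$n_neighbors))
    # sign convention + unit scale
    ref <- rowMeans(x)
    for (c in seq_len(ncol(y))) {
      s <- stats::sd(y[, c])
      if (s == 0) stop("ROI ", roi_id, ": degenerate embedding component ", c)
      if (stats::cor(y[, c], ref) < 0) y[, c] <- -y[, c]
      y[, c] <- (y[, c] - mean(y[, c])) / stats::sd(y[, c])
    }
  }
  dimnames(y) <- NULL
  y
}

# Isomap: geodesic distances on a symmetrized k-NN graph, then classical MDS.
# Disconnected graphs (possible at small k) are bridged by repeatedly adding
# the shortest Euclidean edge between components, in the spirit of vegan's
# stepacross().
embed_isomap <- function(x, d, k) {
  n <- nrow(x)
  k <- max(1L, min(k, n - 1L))
  D <- as.matrix(stats::dist(x))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  W <- D * adj
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  while (comp$no > 1) {
    a <- which(comp$membership == 1)
    b <- which(comp$membership != 1)
    sub <- D[a, b, drop = FALSE]
    hit <- arrayInd(which.min(sub), dim(sub))
    g <- igraph::add_edges(g, c(a[hit[1]], b[hit[2]]),
                           weight = D[a[hit[1]], b[hit[2]]])
    comp <- igraph::components(g)
  }
  G <- igraph::distances(g)
  y <- stats::cmdscale(G, k = d)
  if (ncol(y) < d)
    stop("isomap produced fewer than ", d, " usable components")
  y
}

embed_tsne <- function(x, d, perplexity, seed) {
  if (d > 3) stop("t-SNE supports at most 3 components")
  n <- nrow(x)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 1) stop("too few timepoints for t-SNE")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  Rtsne::Rtsne(x, dims = d, perplexity = perplexity, theta = 0.0,
               check_duplicates = FALSE, pca = TRUE, max_iter = 500,
               verbose = FALSE, num_threads = 1)$Y
}

# Locally-linear embedding (Roweis & Saul): reconstruction weights from the
# regularized local Gram matrix, embedding from the bottom eigenvectors of
# (I - W)'(I - W), skipping the constant eigenvector.
embed_lle <- function(x, d, k) {
  n <- nrow(x)
  k <- max(2L, min(k, n - 1L))
  D <- as.matrix(stats::dist(x))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    Z <- sweep(x[nb, , drop = FALSE], 2, x[i, ])
    G <- tcrossprod(Z)
    G <- G + diag(k) * (sum(diag(G)) + 1e-12) * 1e-3
    w <- solve(G, rep(1, k))
    W[i, nb] <- w / sum(w)
  }
  M <- crossprod(diag(n) - W)
  e <- eigen(M, symmetric = TRUE)
  idx <- seq(n - 1L, n - d) # skip the constant bottom eigenvector
  e$vectors[, idx, drop = FALSE] * sqrt(n)
}

#' High-pass filter a time course
#'
#' Subtracts a centered moving-average baseline, removing slow drifts while
#' preserving high-frequency content. At the edges the window shrinks
#' symmetrically (half-width `min(floor(window/2), t - 1, T - t)`), so the
#' baseline of any linear trend is exact everywhere and a ramp maps to zero.
#'
#' @param series Numeric vector or T x d matrix (filtered per column).
#' @param window Nominal window width in timepoints, `1 < window < T`.
#' @return Filtered series, same shape as the input.
#' @export
highpass_filter <- function(series, window) {
  vec <- is.null(dim(series))
  x <- as.matrix(series)
  Tn <- nrow(x)
  if (window <= 1 || window >= Tn)
    stop("window must satisfy 1 < window < T (got ", window, ", T = ", Tn, ")")
  half <- floor(window / 2)
  t <- seq_len(Tn)
  h <- pmin(half, t - 1L, Tn - t)
  cs <- rbind(0, apply(x, 2, cumsum))
  lo <- t - h; hi <- t + h
  baseline <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (2 * h + 1)
  out <- x - baseline
  if (vec) drop(out) else out
}

#' Standardize columns to mean 0, sd 1
#'
#' Sample (n-1) standard-deviation convention. Constant columns cannot be
#' standardized and raise an error naming the column.
#'
#' @param x Numeric matrix (a vector is treated as one column).
#' @return Matrix of the same shape with each column centered and scaled.
#' @export
standardize_columns <- function(x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- colnames(x)[bad] %||% as.character(bad)
    stop("constant column(s): ", paste(nm, collapse = ", "))
  }
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  if (vec) drop(out) else out
}

#' Reduce every ROI of every subject
#'
#' Applies [reduce_roi()] to each ROI, then the feature-vector preprocessing
#' in the stated order: high-pass filtering followed by column
#' standardization.
#'
#' @param dataset A `roi_dataset`.
#' @param params A [reduction_params()].
#' @param highpass_window `"auto"` (T/4), a window width, or `NULL` to skip
#'   filtering.
#' @param standardize Re-standardize after filtering (default TRUE).
#' @return List (one per subject) of named lists region -> T x d matrix, with
#'   subject ids and groups as attributes `"subject_id"` / `"group"`.
#' @export
reduce_dataset <- function(dataset, params = reduction_params(),
                           highpass_window = "auto", standardize = TRUE) {
  stopifnot(inherits(dataset, "roi_dataset"))
  lapply(dataset$subjects, function(sub) {
    red <- lapply(names(sub$series), function(rid) {
      y <- reduce_roi(sub$series[[rid]], params, roi_id = rid)
      if (!is.null(highpass_window)) {
        w <- if (identical(highpass_window, "auto"))
          max(3L, floor(nrow(y) / 4)) else highpass_window
        y <- highpass_filter(y, w)
      }
      if (standardize) y <- standardize_columns(y)
      y
    })
    names(red) <- names(sub$series)
    attr(red, "subject_id") <- sub$subject_id
    attr(red, "group") <- sub$group
    red
  })
}

#' Connectivity profiles for a whole dataset
#'
#' Convenience wrapper: reduction + preprocessing + per-subject
#' [connectivity_profile()], returning a [build_feature_matrix()] result.
#'
#' @inheritParams reduce_dataset
#' @return A `feature_matrix`.
#' @export
dataset_feature_matrix <- function(dataset, params = reduction_params(),
                                   highpass_window = "auto",
                                   standardize = TRUE) {
  reduced <- reduce_dataset(dataset, params, highpass_window, standardize)
  profiles <- lapply(reduced, function(r)
    connectivity_profile(r, subject_id = attr(r, "subject_id"),
                         group = attr(r, "group")))
  build_feature_matrix(profiles, atlas = dataset$atlas)
}

#' Compare dimensionality-reduction methods end to end
#'
#' Runs the full downstream pipeline (reduction, connectivity features,
#' leave-one-out random-forest classification with the unclassified band)
#' once per method under identical seeds, and tabulates the outcome counts.
#' This is the harness used to decide which embedding best preserves the
#' group-discriminative connectivity structure.
#'
#' @param dataset A two-group `roi_dataset`.
#' @param methods Character vector of reduction methods (>= 2).
#' @param params Template [reduction_params()] supplying the shared settings.
#' @param forest [forest_params()] for the classifier.
#' @param band Unclassified vote-fraction band.
#' @inheritParams reduce_dataset
#' @return `data.frame` with one row per method: `method`, `correct`,
#'   `false`, `unclassified`.
#' @export
compare_reduction_methods <- function(dataset, methods,
                                      params = reduction_params(),
                                      forest = forest_params(),
                                      band = c(0.45, 0.55),
                                      highpass_window = "auto",
                                      standardize = TRUE) {
  if (length(methods) < 2) stop("need at least 2 methods to compare")
  groups <- vapply(dataset$subjects, `[[`, character(1), "group")
  if (length(unique(groups)) != 2)
    stop("method comparison expects a two-group dataset")

  rows <- lapply(methods, function(m) {
    p <- params; p$method <- m
    fm <- dataset_feature_matrix(dataset, p, highpass_window, standardize)
    res <- loo_classify(fm, forest, band)
    cbind(data.frame(method = m), res$summary[, c("correct", "false",
                                                  "unclassified")])
  })
  do.call(rbind, rows)
}
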
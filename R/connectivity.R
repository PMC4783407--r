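#' Pearson correlation between two series
#'
#' Sample Pearson correlation, the connection strength between two ROI time
#' courses. Thin wrapper around [stats::cor()] that enforces the pipeline's
#' preconditions (equal length, at least 3 points, non-constant input).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3) stop("series must have length >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: correlation undefined")
  stats::cor(x, y)
}

#' Fisher z-transformation
#'
#' Variance-stabilizing transform of a correlation coefficient,
#' z = 0.5 * log((1 + rho) / (1 - rho)). Values of |rho| at (or within
#' `clip` of) 1 are clipped to 1 - `clip` so that z stays finite on
#' degenerate inputs.
#'
#' @param rho Numeric vector of correlations in \[-1, 1\].
#' @param clip Clipping margin applied to |rho| before the transform.
#' @return Fisher-z values, same length as `rho`.
#' @export
fisher_z <- function(rho, clip = 1e-7) {
  if (any(abs(rho) > 1)) stop("correlation outside [-1, 1]")
  rho <- pmin(pmax(rho, -1 + clip), 1 - clip)
  0.5 * log((1 + rho) / (1 - rho))
}

#' Feature index for all unordered ROI pairs
#'
#' Enumerates the upper triangle of an R x R connectivity matrix in row-major
#' order: (1,2), (1,3), ..., (1,R), (2,3), ... Feature ids are 1-based. The
#' map is a bijection so any feature can be backtracked to its ROI pair.
#'
#' @param n_rois Number of ROIs (>= 2).
#' @return `data.frame` with columns `feature_id`, `region_i`, `region_j`
#'   (`region_i < region_j`), one row per unordered pair.
#' @export
pair_index <- function(n_rois) {
  if (n_rois < 2) stop("need at least 2 ROIs")
  ij <- which(upper.tri(diag(n_rois)), arr.ind = TRUE)
  ord <- order(ij[, 1], ij[, 2]) # row-major
  data.frame(feature_id = seq_len(nrow(ij)),
             region_i = ij[ord, 1], region_j = ij[ord, 2])
}

#' @describeIn pair_index Feature id of the pair (i, j), i < j.
#' @param i,j ROI ids with `i < j`.
#' @export
pair_to_index <- function(i, j, n_rois) {
  stopifnot(all(i >= 1), all(j <= n_rois))
  if (any(i >= j)) stop("need region_i < region_j")
  (i - 1L) * n_rois - (i * (i - 1L)) %/% 2L + (j - i)
}

#' @describeIn pair_index ROI pair of feature id `k` (backtracking).
#' @param k Feature id in `1..n_rois*(n_rois-1)/2`.
#' @export
index_to_pair <- function(k, n_rois) {
  P <- (n_rois * (n_rois - 1L)) %/% 2L
  if (any(k < 1 | k > P)) stop("feature id out of range")
  # smallest i whose block of pairs contains k
  ends <- cumsum(seq(n_rois - 1L, 1L)) # last feature id for each i
  i <- findInterval(k - 1L, c(0L, ends)) # block index
  start <- c(0L, ends)[i]
  j <- i + (k - start)
  cbind(region_i = i, region_j = j)
}

#' Connectivity profile of one subject
#'
#' Correlates every pair of reduced ROI time courses, applies the Fisher
#' z-transformation and flattens the upper triangle of the correlation matrix
#' into a feature vector, keeping the feature-to-pair index for backtracking.
#' For multi-component reductions (d > 1) the T x d component matrix of each
#' ROI is flattened to a single vector of length T*d before correlating.
#'
#' @param reduced Named list mapping region id to a numeric T x d matrix (or
#'   length-T vector); all ROIs must have identical dimensions.
#' @param subject_id,group Subject annotation carried into the profile.
#' @return Object of class `connectivity_profile`: list with `z` (length
#'   R(R-1)/2 Fisher-z vector), `pairs` (the [pair_index()] table),
#'   `subject_id` and `group`.
#' @export
connectivity_profile <- function(reduced, subject_id = NA_character_,
                                 group = NA_character_) {
  R <- length(reduced)
  if (R < 2) stop("need at least 2 ROIs")
  series <- lapply(reduced, function(m) as.vector(as.matrix(m)))
  len <- lengths(series)
  if (length(unique(len)) != 1L)
    stop("all ROI series must have equal length")

  pairs <- pair_index(R)
  rho <- vapply(seq_len(nrow(pairs)), function(p) {
    pearson_cor(series[[pairs$region_i[p]]], series[[pairs$region_j[p]]])
  }, numeric(1))

  structure(list(z = fisher_z(rho), pairs = pairs,
                 region_ids = names(reduced) %||% as.character(seq_len(R)),
                 subject_id = subject_id, group = group),
            class = "connectivity_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble per-subject profiles into a feature matrix
#'
#' Rows are subjects in input order, columns the R(R-1)/2 Fisher-z features.
#' Column annotation (ROI pair per feature) is carried so that any later
#' subsetting can still be backtracked to brain regions.
#'
#' @param profiles List of [connectivity_profile()] objects sharing one atlas.
#' @param atlas Optional atlas table (see [make_atlas_labels()]) used to name
#'   features "regionA|regionB".
#' @return Object of class `feature_matrix`: list with `x` (subjects x
#'   features matrix), `groups` (factor), `pairs` (feature annotation).
#' @export
build_feature_matrix <- function(profiles, atlas = NULL) {
  if (length(profiles) == 0) stop("no profiles given")
  P <- vapply(profiles, function(p) length(p$z), integer(1))
  if (length(unique(P)) != 1L)
    stop("profiles have mismatched feature counts: ",
         paste(unique(P), collapse = ", "))

  x <- do.call(rbind, lapply(profiles, `[[`, "z"))
  rownames(x) <- vapply(profiles, `[[`, character(1), "subject_id")
  pairs <- profiles[[1]]$pairs
  pairs$name <- if (!is.null(atlas)) {
    lab <- paste0(atlas$name, "/", atlas$side)
    paste0(lab[pairs$region_i], "|", lab[pairs$region_j])
  } else {
    paste0("roi", pairs$region_i, "|roi", pairs$region_j)
  }
  colnames(x) <- pairs$name

  groups <- factor(vapply(profiles, `[[`, character(1), "group"))
  structure(list(x = x, groups = groups, pairs = pairs, atlas = atlas),
            class = "feature_matrix")
}

#' Restrict a feature matrix to a set of features
#'
#' @param fm A `feature_matrix`.
#' @param feature_ids Feature ids (columns) to keep, in the given order.
#' @return A `feature_matrix` with the selected columns; pair annotations are
#'   subset consistently (original feature ids are preserved in `pairs`).
#' @export
subset_features <- function(fm, feature_ids) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(feature_ids) == 0) stop("refusing to build a 0-feature matrix")
  if (any(feature_ids < 1 | feature_ids > ncol(fm$x)))
    stop("feature id out of range")
  fm$x <- fm$x[, feature_ids, drop = FALSE]
  fm$pairs <- fm$pairs[feature_ids, , drop = FALSE]
  fm
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$x), " subjects x ", ncol(x$x),
      " Fisher-z features; groups: ",
      paste(sprintf("%s=%d", levels(x$groups), table(x$groups)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
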
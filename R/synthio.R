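#' Atlas label table
#'
#' Builds the table of ROI labels the pipeline reports against. For the
#' default 45-region atlas the lateralized structures known to matter in
#' rodent opioid pharmacology (sensorimotor, cingulate, entorhinal and insular
#' cortices, hippocampus, ventral/posterior thalamus, hypothalamus, caudate
#' putamen, basolateral/anterior amygdala, nucleus accumbens,
#' superior/inferior colliculus) come first, padded with generically named
#' bilateral pairs to reach `n_rois`.
#'
#' @param n_rois Number of regions (>= 2); default 45.
#' @return `data.frame` with columns `region_id` (1..n_rois), `name`, `side`
#'   (one of "left", "right", "midline").
#' @export
make_atlas_labels <- function(n_rois = 45) {
  if (n_rois < 2) stop("need at least 2 regions")

  lateralized <- c(
    "sensorimotor cortex", "entorhinal cortex", "insula", "hippocampus",
    "thalamus ventral", "thalamus posterior", "hypothalamus",
    "caudate putamen", "amygdala basolateral", "amygdala anterior",
    "nucleus accumbens", "superior colliculus", "inferior colliculus")
  name <- c("anterior cingulate cortex",
            rep(lateralized, each = 2))
  side <- c("midline", rep(c("left", "right"), length(lateralized)))

  if (n_rois > length(name)) {
    extra <- n_rois - length(name)
    k <- ceiling(extra / 2)
    pad_name <- rep(paste0("region ", seq_len(k)), each = 2)[seq_len(extra)]
    pad_side <- rep(c("left", "right"), k)[seq_len(extra)]
    name <- c(name, pad_name)
    side <- c(side, pad_side)
  }
  data.frame(region_id = seq_len(n_rois),
             name = name[seq_len(n_rois)],
             side = side[seq_len(n_rois)],
             stringsAsFactors = FALSE)
}

#' Synthetic-dataset configuration
#'
#' The stated world of the generator: a three-group pharmacological fMRI
#' study (saline n = 13, low dose n = 12, high dose n = 12), 45 ROIs, 600
#' timepoints at TR 2.5 s. Group effects are planted on the Fisher-z scale
#' on a small set of ROI pairs so that dose ordering composes additively:
#' the latent correlation of a planted pair in group g is
#' `tanh(atanh(base_corr) + effect_dz[g])`.
#'
#' @param n_rois,n_timepoints,tr,voxels_per_roi Dataset geometry.
#' @param group_sizes Named integer vector, subjects per group.
#' @param base_corr Baseline latent inter-ROI correlation.
#' @param planted_edges Integer matrix / 2-column data.frame of ROI pairs that
#'   carry the group effect. Default: five disjoint pairs among the first ten
#'   regions.
#' @param effect_dz Named numeric vector, Fisher-z shift per group on planted
#'   edges. Default saline 0, LD 0.5, HD 1.0 (dose-ordered).
#' @param voxel_noise_sd Per-voxel white-noise SD added to the unit-variance
#'   latent ROI signal.
#' @param ar1_coef AR(1) coefficient applied to each voxel series (temporal
#'   autocorrelation typical of fMRI); variance renormalized.
#' @param drift_amplitude Amplitude of a per-voxel linear scanner drift.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   full configuration.
#' @return Object of class `synth_config` (validated list).
#' @export
synth_config <- function(n_rois = 45, n_timepoints = 600, tr = 2.5,
                         voxels_per_roi = 20,
                         group_sizes = c(saline = 13, LD = 12, HD = 12),
                         base_corr = 0.1,
                         planted_edges = cbind(c(1, 3, 5, 7, 9),
                                               c(2, 4, 6, 8, 10)),
                         effect_dz = c(saline = 0, LD = 0.5, HD = 1.0),
                         voxel_noise_sd = 1.0, ar1_coef = 0.3,
                         drift_amplitude = 0.5, seed = 1L) {
  planted_edges <- as.matrix(planted_edges)
  storage.mode(planted_edges) <- "integer"
  cfg <- structure(list(
    n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
    tr = tr, voxels_per_roi = as.integer(voxels_per_roi),
    group_sizes = group_sizes, base_corr = base_corr,
    planted_edges = planted_edges, effect_dz = effect_dz,
    voxel_noise_sd = voxel_noise_sd, ar1_coef = ar1_coef,
    drift_amplitude = drift_amplitude, seed = as.integer(seed)),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_rois < 2) stop("n_rois must be >= 2")
    if (n_timepoints < 4) stop("n_timepoints must be >= 4")
    if (voxels_per_roi < 1) stop("voxels_per_roi must be >= 1")
    if (abs(base_corr) >= 1) stop("base_corr must be in (-1, 1)")
    if (is.null(names(group_sizes)) || any(names(group_sizes) == ""))
      stop("group_sizes must be named")
    if (any(group_sizes < 1)) stop("group sizes must be positive")
    if (!all(names(group_sizes) %in% names(effect_dz)))
      stop("effect_dz must name every group")
    if (nrow(planted_edges) > 0) {
      if (ncol(planted_edges) != 2) stop("planted_edges needs 2 columns")
      if (any(planted_edges < 1 | planted_edges > n_rois))
        stop("planted edge references invalid ROI id")
      if (any(planted_edges[, 1] == planted_edges[, 2]))
        stop("planted edge must join two distinct ROIs")
    }
    if (ar1_coef < 0 || ar1_coef >= 1) stop("ar1_coef must be in [0, 1)")
    if (voxel_noise_sd < 0) stop("voxel_noise_sd must be >= 0")
  })
  invisible(cfg)
}

#' Repair a correlation matrix to positive definiteness
#'
#' Eigenvalue clipping at `eps` followed by re-normalization to unit
#' diagonal. Matrices that are already positive definite are returned
#' unchanged.
#'
#' @param C Symmetric correlation matrix.
#' @param eps Eigenvalue floor.
#' @keywords internal
repair_correlation <- function(C, eps = 1e-6) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) > eps) return(C)
  v <- pmax(e$values, eps)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  e2 <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (e2 <= 0) stop("correlation matrix could not be repaired")
  M
}

group_correlation_matrix <- function(cfg, group) {
  C <- matrix(cfg$base_corr, cfg$n_rois, cfg$n_rois)
  diag(C) <- 1
  if (nrow(cfg$planted_edges) > 0) {
    z <- atanh(cfg$base_corr) + cfg$effect_dz[[group]]
    for (k in seq_len(nrow(cfg$planted_edges))) {
      i <- cfg$planted_edges[k, 1]; j <- cfg$planted_edges[k, 2]
      C[i, j] <- C[j, i] <- tanh(z)
    }
  }
  repair_correlation(C)
}

#' Generate a synthetic multi-subject ROI time-series dataset
#'
#' For each subject, a zero-mean multivariate-normal latent signal is drawn
#' with the group's correlation matrix; each voxel series is the latent ROI
#' signal plus independent Gaussian noise, optionally AR(1)-filtered
#' (variance-preserving, applied identically to all series so zero-lag
#' correlations are unchanged in expectation) with an added per-voxel linear
#' drift. Deterministic given the configuration (including its seed).
#'
#' @param config A [synth_config()].
#' @return Object of class `roi_dataset`: list with `subjects` (each a list
#'   with `subject_id`, `group`, `series` = named list of T x V matrices),
#'   `atlas`, `tr`, and the generating `config`.
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  cfg <- config
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed)

  atlas <- make_atlas_labels(cfg$n_rois)
  chol_by_group <- lapply(names(cfg$group_sizes), function(g)
    chol(group_correlation_matrix(cfg, g)))
  names(chol_by_group) <- names(cfg$group_sizes)

  Tn <- cfg$n_timepoints; V <- cfg$voxels_per_roi; R <- cfg$n_rois
  tgrid <- seq(-1, 1, length.out = Tn)
  scale_ar <- sqrt(1 - cfg$ar1_coef^2)

  subjects <- list()
  for (g in names(cfg$group_sizes)) {
    for (s in seq_len(cfg$group_sizes[[g]])) {
      latent <- matrix(stats::rnorm(Tn * R), Tn, R) %*% chol_by_group[[g]]
      series <- lapply(seq_len(R), function(r) {
        m <- latent[, r] + matrix(stats::rnorm(Tn * V, sd = cfg$voxel_noise_sd),
                                  Tn, V)
        if (cfg$ar1_coef > 0) {
          m <- apply(m, 2, function(x)
            stats::filter(x * scale_ar, cfg$ar1_coef,
                          method = "recursive"))
        }
        if (cfg$drift_amplitude > 0) {
          slopes <- stats::runif(V, -1, 1) * cfg$drift_amplitude
          m <- m + outer(tgrid, slopes)
        }
        m
      })
      names(series) <- as.character(seq_len(R))
      subjects[[length(subjects) + 1L]] <- list(
        subject_id = sprintf("%s_%02d", g, s), group = g, series = series)
    }
  }

  structure(list(subjects = subjects, atlas = atlas, tr = cfg$tr,
                 config = cfg),
            class = "roi_dataset")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' @export
print.roi_dataset <- function(x, ...) {
  n <- length(x$subjects)
  grp <- table(vapply(x$subjects, `[[`, character(1), "group"))
  d <- dim(x$subjects[[1]]$series[[1]])
  cat("<roi_dataset> ", n, " subjects (",
      paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "), ",
      nrow(x$atlas), " ROIs, T=", d[1], " x V=", d[2],
      ", TR=", x$tr, "s\n", sep = "")
  invisible(x)
}

#' Write / read a dataset directory
#'
#' Plain-text, language-neutral layout: `manifest.tsv` (subject_id, group,
#' one relative path per ROI series file), `atlas.tsv`, and one TSV per
#' subject per ROI (rows = timepoints, columns = voxels). Numeric values
#' round-trip at full double precision.
#'
#' @param dataset A `roi_dataset`.
#' @param dir Target directory (created if needed).
#' @return `write_dataset`: the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "roi_dataset"))
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(dataset$atlas, file.path(dir, "atlas.tsv"), sep = "\t")

  rows <- list()
  for (sub in dataset$subjects) {
    for (rid in names(sub$series)) {
      rel <- file.path("series", sprintf("%s_roi%s.tsv", sub$subject_id, rid))
      data.table::fwrite(as.data.frame(sub$series[[rid]]),
                         file.path(dir, rel), sep = "\t")
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sub$subject_id, group = sub$group,
        region_id = as.integer(rid), path = rel)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  data.table::fwrite(manifest, mpath, sep = "\t")
  tr_dt <- data.frame(key = "tr", value = dataset$tr)
  data.table::fwrite(tr_dt, file.path(dir, "meta.tsv"), sep = "\t")
  invisible(mpath)
}

#' @rdname write_dataset
#' @return `read_dataset`: the reconstructed `roi_dataset`.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop("no manifest.tsv in ", dir)
  manifest <- as.data.frame(data.table::fread(mpath, sep = "\t"))
  atlas <- as.data.frame(data.table::fread(file.path(dir, "atlas.tsv"),
                                           sep = "\t"))
  meta <- as.data.frame(data.table::fread(file.path(dir, "meta.tsv"),
                                          sep = "\t"))
  tr <- as.numeric(meta$value[meta$key == "tr"])

  missing <- !file.exists(file.path(dir, manifest$path))
  if (any(missing))
    stop("manifest references missing files for subject(s): ",
         paste(unique(manifest$subject_id[missing]), collapse = ", "))

  subjects <- lapply(split(manifest, manifest$subject_id)[
    unique(manifest$subject_id)], function(mf) {
    series <- lapply(seq_len(nrow(mf)), function(r)
      as.matrix(data.table::fread(file.path(dir, mf$path[r]), sep = "\t")))
    names(series) <- as.character(mf$region_id)
    series <- series[order(as.integer(names(series)))]
    names(series) <- as.character(sort(as.integer(mf$region_id)))
    list(subject_id = mf$subject_id[1], group = unique(mf$group), series = series)
  })
  names(subjects) <- NULL

  Ts <- unlist(lapply(subjects, function(s) vapply(s$series, nrow, integer(1))))
  if (length(unique(Ts)) != 1L)
    stop("heterogeneous timepoint counts across subjects/ROIs: ",
         paste(unique(Ts), collapse = ", "))
  Rs <- vapply(subjects, function(s) length(s$series), integer(1))
  if (length(unique(Rs)) != 1L)
    stop("subjects do not share the same ROI set")

  structure(list(subjects = subjects, atlas = atlas, tr = tr, config = NULL),
            class = "roi_dataset")
}

#' Extract per-ROI voxel time series from a labelled 4D volume
#'
#' Pulls, for every nonzero label in `label_volume`, the time series of all
#' voxels carrying that label from a 4D array (x, y, z, t). Voxels are
#' ordered lexicographically by spatial index (x first, then y, then z) for
#' reproducibility.
#'
#' @param image_4d 4D numeric array (x, y, z, t).
#' @param label_volume 3D integer array on the same spatial grid; 0 is
#'   background.
#' @param labels Labels to extract; default all nonzero labels present.
#' @param subject_id,group Annotation for the returned record.
#' @return Subject record: list with `subject_id`, `group`, `series` (named
#'   list label -> T x V matrix).
#' @export
extract_roi_series <- function(image_4d, label_volume, labels = NULL,
                               subject_id = NA_character_,
                               group = NA_character_) {
  di <- dim(image_4d); dl <- dim(label_volume)
  if (length(di) != 4 || length(dl) != 3 || !all(di[1:3] == dl))
    stop("image and label volume must share the same spatial grid")
  if (any(label_volume < 0) || any(label_volume != round(label_volume)))
    stop("labels must be non-negative integers")

  present <- sort(unique(as.integer(label_volume[label_volume > 0])))
  if (length(present) == 0) stop("label volume contains no nonzero labels")
  if (is.null(labels)) labels <- present
  absent <- setdiff(labels, present)
  if (length(absent) > 0)
    stop("label(s) absent from volume: ", paste(absent, collapse = ", "))

  Tn <- di[4]
  flat <- matrix(image_4d, prod(di[1:3]), Tn) # voxels x time, column-major
  series <- lapply(labels, function(lab) {
    ind <- which(label_volume == lab, arr.ind = TRUE)
    ord <- order(ind[, 1], ind[, 2], ind[, 3]) # lexicographic (x, y, z)
    ind <- ind[ord, , drop = FALSE]
    lin <- ind[, 1] + (ind[, 2] - 1L) * di[1] + (ind[, 3] - 1L) * di[1] * di[2]
    t(flat[lin, , drop = FALSE]) # T x V
  })
  names(series) <- as.character(labels)
  list(subject_id = subject_id, group = group, series = series)
}
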
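# Connectivity-based parcellation of an ROI.
#
# Each ROI voxel gets a connectivity fingerprint: its Pearson correlation
# with every gray-matter target voxel. A second-order correlation matrix
# (similarity between fingerprints) is computed per subject, averaged across
# subjects in identical voxel order, and clustered with k-means (k-means++
# seeding, squared-Euclidean distance, replicate restarts keeping the
# minimum-inertia solution). Labels are canonicalized along the ROI long
# axis and isolated satellite components are pruned.

#' Parcellation configuration
#'
#' @param k Number of clusters (>= 2; the long-axis analysis uses 2).
#' @param n_replicates Number of k-means restarts with fresh random seeds;
#'   the minimum-inertia labeling wins.
#' @param max_iterations Lloyd iteration cap per replicate.
#' @param rng_seed Integer; replicate r is seeded with `rng_seed + r`.
#' @param prune_connectivity Neighbourhood for pruning components: 6, 18, 26.
#' @param prune_min_fraction Components smaller than this fraction of the
#'   largest component of either cluster are pruned.
#' @param include_roi_in_targets Whether ROI voxels may appear among the
#'   fingerprint target voxels (default `FALSE`: a voxel's fingerprint is
#'   its connectivity to gray matter outside the ROI).
#' @return A list of class `parcellation_config`.
#' @export
parcellation_config <- function(k = 2, n_replicates = 25,
                                max_iterations = 100, rng_seed = 1L,
                                prune_connectivity = 26,
                                prune_min_fraction = 0.05,
                                include_roi_in_targets = FALSE) {
  stopifnot(k >= 2, n_replicates >= 1, max_iterations >= 1,
            prune_connectivity %in% c(6, 18, 26),
            prune_min_fraction >= 0, prune_min_fraction < 1)
  structure(list(k = as.integer(k), n_replicates = as.integer(n_replicates),
                 max_iterations = as.integer(max_iterations),
                 rng_seed = as.integer(rng_seed),
                 prune_connectivity = prune_connectivity,
                 prune_min_fraction = prune_min_fraction,
                 include_roi_in_targets = include_roi_in_targets),
            class = "parcellation_config")
}

#' Connectivity fingerprints of ROI voxels
#'
#' Pearson correlation of every ROI voxel's time series with every target
#' voxel's series. Zero-variance series cannot be correlated: affected ROI
#' voxels (rows) or target voxels (columns) are dropped with a warning and
#' recorded in the result.
#'
#' @param roi_series V_roi x T matrix (unsmoothed ROI voxel series).
#' @param target_series V_target x T matrix (smoothed gray-matter series).
#' @return A `fingerprint_matrix`: list with `values` (V_roi x V_target
#'   correlations), `dropped_roi`, `dropped_target` (indices into the input
#'   rows that were removed).
#' @export
compute_fingerprints <- function(roi_series, target_series) {
  roi_series <- as.matrix(roi_series)
  target_series <- as.matrix(target_series)
  stopifnot(ncol(roi_series) == ncol(target_series), ncol(roi_series) >= 3)
  sd_r <- apply(roi_series, 1, stats::sd)
  sd_t <- apply(target_series, 1, stats::sd)
  dropped_roi <- which(sd_r == 0 | !is.finite(sd_r))
  dropped_target <- which(sd_t == 0 | !is.finite(sd_t))
  if (length(dropped_roi) || length(dropped_target))
    warning("dropping zero-variance series: ", length(dropped_roi),
            " ROI voxel(s), ", length(dropped_target), " target voxel(s)",
            call. = FALSE)
  if (length(dropped_roi))
    roi_series <- roi_series[-dropped_roi, , drop = FALSE]
  if (length(dropped_target))
    target_series <- target_series[-dropped_target, , drop = FALSE]
  vals <- stats::cor(t(roi_series), t(target_series))
  structure(list(values = vals, dropped_roi = dropped_roi,
                 dropped_target = dropped_target),
            class = "fingerprint_matrix")
}

#' Second-order correlation matrix of fingerprints
#'
#' Entry (i, i') is the Pearson correlation between the fingerprints of ROI
#' voxels i and i'; the diagonal is forced to exactly 1. Constant
#' fingerprint rows are dropped with a record.
#'
#' @param fingerprints A `fingerprint_matrix` or plain V_roi x V_target
#'   matrix.
#' @return A `second_order_matrix`: list with `values` (V_roi x V_roi) and
#'   `dropped_roi`.
#' @export
second_order <- function(fingerprints) {
  vals <- if (inherits(fingerprints, "fingerprint_matrix"))
    fingerprints$values else as.matrix(fingerprints)
  stopifnot(nrow(vals) >= 2)
  sds <- apply(vals, 1, stats::sd)
  dropped <- which(sds == 0 | !is.finite(sds))
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " constant fingerprint row(s) from the second-order matrix",
            call. = FALSE)
    vals <- vals[-dropped, , drop = FALSE]
  }
  m <- stats::cor(t(vals))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  structure(list(values = m, dropped_roi = dropped),
            class = "second_order_matrix")
}

#' Average second-order matrices across subjects
#'
#' Element-wise mean; all inputs must share dimension (the caller guarantees
#' identical canonical voxel order, which the pipeline enforces by
#' construction).
#'
#' @param matrices List of `second_order_matrix` objects or plain matrices.
#' @return A `second_order_matrix`.
#' @export
group_average <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  vals <- lapply(matrices, function(m)
    if (inherits(m, "second_order_matrix")) m$values else as.matrix(m))
  d <- dim(vals[[1]])
  for (i in seq_along(vals)) {
    if (!identical(dim(vals[[i]]), d))
      stop("matrix ", i, " has dimension ",
           paste(dim(vals[[i]]), collapse = "x"), ", expected ",
           paste(d, collapse = "x"), " (first differing voxel: ",
           min(which(dim(vals[[i]]) != d)), ")", call. = FALSE)
  }
  avg <- Reduce(`+`, vals) / length(vals)
  structure(list(values = avg, dropped_roi = integer(0)),
            class = "second_order_matrix")
}

# ---- k-means ---------------------------------------------------------------

# squared Euclidean distances from rows of x to rows of centers
sq_dist <- function(x, centers) {
  d <- outer(rowSums(x^2), rowSums(centers^2), `+`) -
    2 * x %*% t(centers)
  pmax(d, 0)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  first <- sample.int(n, 1)
  centers[1, ] <- x[first, ]
  d2 <- sq_dist(x, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, sq_dist(x, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

lloyd <- function(x, centers, max_iterations) {
  k <- nrow(centers)
  assign <- rep(0L, nrow(x))
  for (it in seq_len(max_iterations)) {
    d <- sq_dist(x, centers)
    new_assign <- max.col(-d, ties.method = "first")
    # re-seed any emptied centroid at the point farthest from its centroid
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {
        far <- which.max(d[cbind(seq_len(nrow(x)), new_assign)])
        centers[j, ] <- x[far, ]
        new_assign[far] <- j
      }
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  d <- sq_dist(x, centers)
  list(labels = assign,
       inertia = sum(d[cbind(seq_len(nrow(x)), assign)]),
       centers = centers)
}

#' k-means parcellation of a second-order matrix
#'
#' Rows of the second-order matrix are the feature vectors. Each replicate
#' draws k-means++ initial centroids and runs Lloyd iterations with squared
#' Euclidean distance; the labeling with the smallest within-cluster sum of
#' squared distances over all replicates is returned. Replicate r uses seed
#' `rng_seed + r`, so results are reproducible.
#'
#' @param matrix A `second_order_matrix` or plain symmetric matrix.
#' @param config A [parcellation_config()].
#' @return A `parcel_labeling`: list with `labels` (integer per ROI voxel),
#'   `inertia`, `k`, `canonical_names` (filled by [relabel_by_axis()]),
#'   `pruned_voxels` (filled by [prune_isolated()]).
#' @export
kmeans_parcellate <- function(matrix, config = parcellation_config()) {
  x <- if (inherits(matrix, "second_order_matrix")) matrix$values
  else as.matrix(matrix)
  stopifnot(nrow(x) > config$k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  best <- NULL
  for (r in seq_len(config$n_replicates)) {
    set.seed(config$rng_seed + r)
    fit <- lloyd(x, kmeanspp_init(x, config$k), config$max_iterations)
    if (length(unique(fit$labels)) < config$k) next
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  if (is.null(best))
    stop("no replicate produced ", config$k, " nonempty clusters",
         call. = FALSE)
  structure(list(labels = best$labels, inertia = best$inertia,
                 k = config$k, canonical_names = NULL,
                 pruned_voxels = integer(0)),
            class = "parcel_labeling")
}

#' @export
print.parcel_labeling <- function(x, ...) {
  cat("<parcel_labeling> k = ", x$k, "; sizes: ",
      paste(tabulate(x$labels, x$k), collapse = ", "),
      "; inertia = ", signif(x$inertia, 6), "\n", sep = "")
  if (!is.null(x$canonical_names))
    cat("  names: ", paste(seq_len(x$k), x$canonical_names, sep = " = ",
                           collapse = ", "), "\n", sep = "")
  if (length(x$pruned_voxels))
    cat("  pruned ", length(x$pruned_voxels), " voxel(s)\n", sep = "")
  invisible(x)
}

#' Canonical anterior/posterior naming of a 2-cluster labeling
#'
#' The cluster whose voxels have the larger mean y coordinate in mm (the
#' more anterior in RAS+ orientation) is named "anterior", the other
#' "posterior". Invariant to permutations of the input label numbers. An
#' exact tie is broken deterministically in favour of the smaller cluster
#' index (and recorded in the result as `tie_broken`).
#'
#' @param labeling A `parcel_labeling` with k = 2.
#' @param roi_voxel_coords Integer matrix (V_roi x 3, 0-based) of the ROI
#'   voxel indices in the labeling's order.
#' @param grid A `volume_grid`.
#' @return The labeling with labels renumbered (1 = anterior, 2 = posterior)
#'   and `canonical_names` set.
#' @export
relabel_by_axis <- function(labeling, roi_voxel_coords, grid) {
  stopifnot(labeling$k == 2,
            nrow(roi_voxel_coords) == length(labeling$labels))
  mm <- voxel_to_mm(roi_voxel_coords, grid)
  my <- vapply(1:2, function(j) mean(mm[labeling$labels == j, "y"]),
               numeric(1))
  tie <- isTRUE(all.equal(my[1], my[2]))
  anterior_first <- if (tie) TRUE else my[1] > my[2]
  out <- labeling
  if (!anterior_first) out$labels <- 3L - labeling$labels
  out$canonical_names <- c("anterior", "posterior")
  out$tie_broken <- tie
  out
}

#' Prune isolated satellite components from a labeling
#'
#' Within each cluster, connected components are found under
#' `prune_connectivity`; components smaller than `prune_min_fraction` of the
#' largest component of either cluster are removed (a reproducible surrogate
#' for removing stray peripheral voxels by inspection).
#'
#' @param labeling A `parcel_labeling`.
#' @param roi_voxel_coords Integer matrix (V_roi x 3, 0-based), one row per
#'   labeled voxel.
#' @param config A [parcellation_config()].
#' @return The labeling with pruned voxels removed from `labels` and listed
#'   (as indices into the original voxel order) in `pruned_voxels`;
#'   `kept_voxels` gives the retained original indices.
#' @export
prune_isolated <- function(labeling, roi_voxel_coords,
                           config = parcellation_config()) {
  stopifnot(nrow(roi_voxel_coords) == length(labeling$labels))
  comp_sizes <- list()
  comp_of <- integer(length(labeling$labels))
  comp_key <- character(length(labeling$labels))
  largest <- 0
  for (j in seq_len(labeling$k)) {
    sel <- which(labeling$labels == j)
    if (!length(sel)) next
    cc <- connected_components(roi_voxel_coords[sel, , drop = FALSE],
                               config$prune_connectivity)
    sizes <- tabulate(cc)
    largest <- max(largest, sizes)
    comp_key[sel] <- paste0(j, ".", cc)
    comp_sizes[[as.character(j)]] <- sizes
  }
  cutoff <- config$prune_min_fraction * largest
  prune <- logical(length(labeling$labels))
  for (j in seq_len(labeling$k)) {
    sizes <- comp_sizes[[as.character(j)]]
    for (c in seq_along(sizes)) {
      if (sizes[c] < cutoff)
        prune[comp_key == paste0(j, ".", c)] <- TRUE
    }
  }
  out <- labeling
  if (any(prune)) {
    for (j in seq_len(labeling$k)) {
      if (all(prune[labeling$labels == j]))
        stop("pruning would empty cluster ", j, "; nothing pruned",
             call. = FALSE)
    }
    out$labels <- labeling$labels[!prune]
    out$pruned_voxels <- which(prune)
    out$kept_voxels <- which(!prune)
  } else {
    out$pruned_voxels <- integer(0)
    out$kept_voxels <- seq_along(labeling$labels)
  }
  out
}

#' Project a labeling back into a volume
#'
#' @param labeling A `parcel_labeling` (possibly pruned).
#' @param roi_mask Logical ROI mask whose canonical voxel order matches the
#'   labeling's original voxel order.
#' @param grid A `volume_grid`.
#' @return Integer array: 0 outside the ROI (and at pruned voxels),
#'   1 = anterior (label 1), 2 = posterior (label 2).
#' @export
labels_to_volume <- function(labeling, roi_mask, grid) {
  check_mask(roi_mask, grid)
  kept <- labeling$kept_voxels
  if (is.null(kept)) kept <- seq_along(labeling$labels)
  n_orig <- length(kept) + length(labeling$pruned_voxels)
  if (sum(roi_mask) != n_orig)
    stop("labeling covers ", n_orig, " voxels but the ROI mask has ",
         sum(roi_mask), call. = FALSE)
  vol <- array(0L, dim = grid$shape)
  vox <- which(roi_mask)
  vol[vox[kept]] <- labeling$labels
  vol
}

#' Recover a labeling from a label volume
#'
#' Inverse of [labels_to_volume()] over the unpruned voxels.
#'
#' @param volume Integer label array (0 background).
#' @param roi_mask Logical ROI mask.
#' @return Integer labels for ROI voxels in canonical order (0 where pruned).
#' @export
volume_to_labels <- function(volume, roi_mask) {
  as.integer(volume[roi_mask])
}

#' Group-level parcellation of an ROI from cleaned runs
#'
#' Convenience wrapper running the full parcellation chain for one ROI:
#' per-subject fingerprints (unsmoothed ROI series against target series),
#' second-order matrices, group averaging, k-means, canonical relabeling and
#' pruning.
#'
#' @param runs_roi Named list of V_roi x T matrices (unsmoothed ROI series
#'   per subject, canonical voxel order).
#' @param runs_target Named list of V_target x T matrices (smoothed target
#'   series per subject, same subjects).
#' @param roi_mask,grid ROI geometry for relabeling/pruning.
#' @param config A [parcellation_config()].
#' @return A `parcel_labeling` with `roi_voxels` (coordinates) attached.
#' @export
parcellate_roi <- function(runs_roi, runs_target, roi_mask, grid,
                           config = parcellation_config()) {
  stopifnot(length(runs_roi) == length(runs_target))
  mats <- lapply(seq_along(runs_roi), function(i) {
    fp <- compute_fingerprints(runs_roi[[i]], runs_target[[i]])
    if (length(fp$dropped_roi))
      stop("subject ", i, ": zero-variance ROI voxel(s) ",
           paste(fp$dropped_roi, collapse = ", "),
           "; per-subject voxel sets must agree before averaging",
           call. = FALSE)
    second_order(fp)
  })
  avg <- group_average(mats)
  lab <- kmeans_parcellate(avg, config)
  coords <- voxel_indices(grid, roi_mask)
  lab <- relabel_by_axis(lab, coords, grid)
  lab <- prune_isolated(lab, coords, config)
  lab$roi_voxels <- coords
  lab
}
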
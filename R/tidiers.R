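# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parcel labeling
#'
#' @param x A `parcel_labeling` (from [parcellate_roi()] or
#'   [kmeans_parcellate()] after relabeling).
#' @param ... Unused.
#' @return Tibble with one row per retained ROI voxel: voxel indices (when
#'   coordinates are attached), integer `label` and `parcel` name.
#' @export
tidy.parcel_labeling <- function(x, ...) {
  nm <- x$canonical_names %||% as.character(seq_len(x$k))
  out <- tibble::tibble(label = x$labels, parcel = nm[x$labels])
  kept <- x$kept_voxels %||% seq_along(x$labels)
  if (!is.null(x$roi_voxels)) {
    cc <- x$roi_voxels[kept, , drop = FALSE]
    out <- dplyr::bind_cols(tibble::as_tibble(cc), out)
  }
  out
}

#' @rdname tidy.parcel_labeling
#' @export
glance.parcel_labeling <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia,
                 n_voxels = length(x$labels),
                 n_pruned = length(x$pruned_voxels))
}

#' Tidy a cluster inference result
#'
#' @param x A `cluster_inference`.
#' @param ... Unused.
#' @return The cluster table (one row per suprathreshold cluster).
#' @export
tidy.cluster_inference <- function(x, ...) x$clusters

#' @rdname tidy.cluster_inference
#' @export
glance.cluster_inference <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$significant),
                 p_map = x$p_map,
                 df = x$df, t_threshold = x$tcrit,
                 n_permutations = x$n_permutations_used,
                 exhaustive = x$exhaustive)
}

#' Tidy a phantom study
#'
#' @param x A `phantom_study`.
#' @param ... Unused.
#' @return The subject table.
#' @export
tidy.phantom_study <- function(x, ...) x$subjects

#' @rdname tidy.phantom_study
#' @export
glance.phantom_study <- function(x, ...) {
  tibble::tibble(n_subjects = length(x$runs),
                 n_groups = length(x$config$n_per_group),
                 n_volumes = x$config$n_volumes,
                 tr_seconds = x$config$tr_seconds,
                 n_roi_voxels = sum(x$roi_mask_left) + sum(x$roi_mask_right))
}
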
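# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a parcel labeling as tiled axial slices
#'
#' @param object A `parcel_labeling` with `roi_voxels` attached.
#' @param ... Unused.
#' @return A ggplot: x/y voxel tiles coloured by parcel, faceted by slice.
#' @export
autoplot.parcel_labeling <- function(object, ...) {
  d <- tidy(object)
  stopifnot(all(c("i", "j", "k") %in% names(d)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                  fill = .data$parcel)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (voxel)", y = "y (voxel)", fill = NULL,
                  title = "Long-axis parcellation") +
    ggplot2::theme_minimal()
}

#' Plot the permutation null against observed cluster sizes
#'
#' @param object A `cluster_inference`.
#' @param ... Unused.
#' @return A ggplot: histogram of null cluster sizes with observed cluster
#'   sizes marked (dashed = not significant, solid = FDR-significant).
#' @export
autoplot.cluster_inference <- function(object, ...) {
  null_df <- tibble::tibble(size = unlist(object$null_sizes))
  if (nrow(null_df) == 0) null_df <- tibble::tibble(size = 0)
  p <- ggplot2::ggplot(null_df, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::labs(x = "suprathreshold cluster size (voxels)", y = "count",
                  title = "Permutation null of cluster sizes") +
    ggplot2::theme_minimal()
  if (nrow(object$clusters))
    p <- p + ggplot2::geom_vline(
      data = object$clusters,
      ggplot2::aes(xintercept = .data$size,
                   linetype = .data$significant),
      colour = "firebrick") +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      name = "FDR significant")
  p
}

#' Scatter plot of connectivity against behavior
#'
#' @param data Tibble with per-subject `z` (connectivity) and behavior
#'   score column.
#' @param score Name of the behavior column.
#' @param group Optional grouping column mapped to colour.
#' @return A ggplot with a least-squares line per group.
#' @export
plot_behavior_correlation <- function(data, score = "behavior",
                                      group = NULL) {
  aes <- ggplot2::aes(x = .data$z, y = .data[[score]])
  if (!is.null(group)) aes$colour <- rlang::sym(group)
  ggplot2::ggplot(data, aes) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "connectivity (Fisher z)", y = score) +
    ggplot2::theme_minimal()
}
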
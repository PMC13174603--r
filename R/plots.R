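# ggplot2 displays for the main result types.

#' @method tidy rsa_simmat
#' @export
tidy.rsa_simmat <- function(x, ...) {
  cats <- attr(x, "categories")
  m <- unclass(x)
  tidyr::expand_grid(
    category_row = factor(cats, levels = cats),
    category_col = factor(cats, levels = cats)
  ) |>
    dplyr::mutate(similarity = as.vector(t(m)))
}

#' Heatmap of a similarity matrix
#'
#' @param object An `rsa_simmat`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rsa_simmat
#' @export
autoplot.rsa_simmat <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$category_col,
    y = .data$category_row, fill = .data$similarity
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "r",
      title = "Cross-validated similarity"
    ) +
    ggplot2::theme_minimal()
}

#' Embedded category configuration in PC space
#'
#' @param object An `embedding`.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 with item labels.
#' @method autoplot embedding
#' @export
autoplot.embedding <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
    label = .data$item
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' Dumbbell-style plot of a partition ranking
#'
#' Partition-model scores in rank order, optionally highlighting named
#' partitions (e.g. `"FB_WPO"`).
#'
#' @param ranking A `partition_ranking` tibble.
#' @param highlight Character vector of partition names to emphasize.
#' @return A ggplot.
#' @export
plot_partition_ranking <- function(ranking, highlight = character(0)) {
  df <- dplyr::mutate(ranking, hl = .data$name %in% highlight)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$name, -.data$rank), color = .data$hl
  )) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "red")) +
    ggplot2::labs(x = "model-similarity correlation", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stability-coupling scatterplot
#'
#' Per-subject coordinates with the identity (equilibrium) line; points
#' above the line are dominated by internal stability, points below by
#' cross-region coupling.
#'
#' @param points Tibble from [coupling_points()].
#' @return A ggplot.
#' @export
plot_coupling <- function(points) {
  ggplot2::ggplot(points, ggplot2::aes(
    .data$coupling, .data$stability,
    color = .data$group
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PFC-VTC coupling", y = "PFC stability") +
    ggplot2::theme_minimal()
}

#' Tissue-metric trajectory across age
#'
#' ROI-mean metric against age with a loess trend.
#'
#' @param roi_means Tibble from [roi_mean()].
#' @return A ggplot.
#' @export
plot_trajectory <- function(roi_means) {
  ggplot2::ggplot(roi_means, ggplot2::aes(.data$age, .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~lobe, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "ROI mean") +
    ggplot2::theme_minimal()
}
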
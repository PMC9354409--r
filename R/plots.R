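# ggplot2 visual summaries: sensor radar profiles, ordination score plots,
# and ROAV contribution bars.

#' Radar plot of mean sensor responses
#'
#' One closed polygon per group over the sensor axes, the standard way to
#' show an e-nose fingerprint.
#'
#' @param x Sensor tibble (see [read_sensor_matrix()]).
#' @param groups Groups to draw (default: all).
#' @param group_col Name of the group-label column.
#' @return A ggplot object.
#' @export
plot_radar <- function(x, groups = NULL, group_col = "group") {
  x <- check_sensor_tbl(x, group_col)
  groups <- groups %||% unique(x[[group_col]])
  prof <- purrr::map(
    setNames(groups, groups),
    function(g) radar_profile(x, g, group_col)
  ) |>
    dplyr::bind_rows(.id = "group")
  prof$sensor <- factor(prof$sensor, levels = sensor_names(x, group_col))
  closing <- prof |>
    dplyr::filter(.data$sensor == levels(prof$sensor)[1])
  ggplot2::ggplot(
    dplyr::bind_rows(prof, closing),
    ggplot2::aes(
      x = .data$sensor, y = .data$mean_response,
      group = .data$group, colour = .data$group, fill = .data$group
    )
  ) +
    ggplot2::geom_polygon(alpha = 0.15, linewidth = 0.6) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "mean response", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Score plot of an e-nose ordination
#'
#' @param object An `enose_ord` from [enose_pca()] or [enose_lda()].
#' @param ... Unused.
#' @return A ggplot object; axis labels carry the explained-variance shares.
#' @export
autoplot.enose_ord <- function(object, ...) {
  axes <- setdiff(names(object$scores), "group")[1:2]
  if (anyNA(axes)) abort("Need at least two axes to plot.")
  lab <- function(a) {
    sprintf("%s (%.2f%%)", a, 100 * object$explained_ratio[[a]])
  }
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(
      x = .data[[axes[1]]], y = .data[[axes[2]]], colour = .data$group
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(axes[1]), y = lab(axes[2]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of ROAV contributions
#'
#' Key and modified odor compounds of one group, ordered by ROAV on a log
#' scale (contributions span four orders of magnitude).
#'
#' @param object A `roav_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roav_tbl <- function(object, ...) {
  d <- as_tibble(object) |>
    dplyr::filter(.data$odor_class %in% c("key", "modified"))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = stats::reorder(.data$compound, .data$roav_high),
      y = .data$roav_high, fill = .data$odor_class
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "ROAV (upper endpoint)",
      title = paste0(
        "Odor contributions, group ", attr(object, "group"),
        " (reference: ", attr(object, "reference"), ")"
      ),
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
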
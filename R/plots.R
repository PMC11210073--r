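#' Barplot of boundary counts per level
#'
#' @param boundaries Boundary tibble.
#' @return A ggplot object.
#' @export
plot_level_histogram <- function(boundaries) {
  hist <- level_histogram(boundaries)
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$level), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "boundary level", y = "boundaries",
                  title = "TAD boundary levels") +
    ggplot2::theme_minimal()
}

#' Barplot of feature-overlap fractions per boundary level
#'
#' @param fractions Tibble from [overlap_fraction_by_level()].
#' @param feature Axis label for the feature (default "DSB peaks").
#' @return A ggplot object.
#' @export
plot_overlap_fractions <- function(fractions, feature = "DSB peaks") {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = factor(.data$level), y = .data$fraction)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "boundary level",
                  y = sprintf("fraction overlapping %s", feature)) +
    ggplot2::theme_minimal()
}

#' Heatmap of mean DSB density by (level, accessibility) subgroup
#'
#' @param summary Tibble from [bin_group_summary()].
#' @return A ggplot object; tiles annotated with the subgroup bin counts.
#' @export
plot_bin_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$dnase_cat),
                               y = factor(.data$level),
                               fill = .data$mean_dsb)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_bins), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "mean DSB\ndensity") +
    ggplot2::labs(x = "accessibility category", y = "bin level") +
    ggplot2::theme_minimal()
}

#' Aggregate signal profile around boundary anchors
#'
#' @param object A `tad_profile` from [profile_matrix()].
#' @param ... Unused.
#' @return A ggplot object: mean signal per offset bin.
#' @method autoplot tad_profile
#' @export
autoplot.tad_profile <- function(object, ...) {
  df <- tibble(
    offset = object$offsets + object$bin_width / 2,
    mean_signal = object$aggregate
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean_signal)) +
    ggplot2::geom_line(color = "darkorange") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from boundary center (bp)",
                  y = "mean signal") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
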
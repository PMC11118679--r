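#' Plot an en-face thickness map
#'
#' Heatmap of per-column tissue thickness on the en-face grid, with axes
#' in mm.
#'
#' @param object A `thickness_map` (see [thickness_map()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thickness_map
#' @export
autoplot.thickness_map <- function(object, ...) {
  df <- tidyr::expand_grid(y = seq_len(nrow(object)),
                           x = seq_len(ncol(object)))
  df$thickness_um <- as.vector(t(unclass(object)))
  df$x_mm <- (df$x - 0.5) * attr(object, "dx_um") / 1000
  df$y_mm <- (df$y - 0.5) * attr(object, "dy_um") / 1000
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$thickness_um)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "thickness (µm)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "En-face thickness map") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.thickness_map
#' @param map A `thickness_map`.
#' @export
plot_thickness_map <- function(map, ...) autoplot.thickness_map(map, ...)

#' Plot a depth-sweep intensity profile
#'
#' Mean B-scan intensity against stage position, with the selected
#' optimum marked.
#'
#' @param object A [depth_stack()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot depth_stack
#' @export
autoplot.depth_stack <- function(object, ...) {
  opt <- find_optimal_depth(object)
  df <- tibble::tibble(
    position = object$positions,
    mean_intensity = vapply(object$frames, mean_frame_intensity, numeric(1)))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$mean_intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = opt$position, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "stage position (mm)", y = "mean B-scan intensity",
                  title = "Depth sweep") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.depth_stack
#' @param stack A [depth_stack()].
#' @export
plot_depth_sweep <- function(stack, ...) autoplot.depth_stack(stack, ...)

#' Plot group readouts of a screen table
#'
#' Per-sample mean readouts by group and timepoint, one panel per readout,
#' with group mean +/- SD overlaid — the standard control-separation view
#' of a screen.
#'
#' @param data Screen tibble (schema of [make_screen_dataset()]).
#' @param readouts Readout columns to include.
#' @return A ggplot object.
#' @export
plot_screen_groups <- function(data,
                               readouts = c("thickness_um", "area_mm2",
                                            "volume_mm3")) {
  keys <- intersect(c("sample_id", "group", "timepoint"), names(data))
  long <- data |>
    tidyr::pivot_longer(dplyr::all_of(readouts), names_to = "readout") |>
    dplyr::summarise(value = mean(.data$value),
                     .by = dplyr::all_of(c(keys, "readout")))
  if (!"timepoint" %in% names(long)) long$timepoint <- "screen"
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        alpha = 0.7) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1),
                          geom = "pointrange", shape = 3,
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~readout, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "readout", colour = "group") +
    ggplot2::theme_minimal()
}
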
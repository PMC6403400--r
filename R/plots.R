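#' Plot an event stream in the x-time plane
#'
#' The standard visualization of a focal sweep: each event as a point at
#' (time, x-column), colored by polarity, collapsing the y dimension. The
#' polarity inversion of every object edge is visible as the meeting point
#' of the two colors.
#'
#' @param object An [event_stream()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.event_stream <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$polarity <- factor(ifelse(df$p > 0, "ON", "OFF"),
                        levels = c("OFF", "ON"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_us / 1e3, y = .data$x,
                                   colour = .data$polarity)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(OFF = "#D55E00",
                                            ON = "#0072B2")) +
    ggplot2::labs(x = "time (ms)", y = "x (pixel column)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a depth map
#'
#' Color-coded metric depth on a perceptually uniform ramp, near depths
#' warm, invalid pixels blank.
#'
#' @param object A [assemble_depth_map()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "plasma", direction = -1,
                                  na.value = "grey92",
                                  name = "depth (m)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' Plot the relative-error distribution of a depth map
#'
#' @param object A `dff_error_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dff_error_report <- function(object, ...) {
  ggplot2::ggplot(object$errors,
                  ggplot2::aes(x = .data$rel_error_pct)) +
    ggplot2::geom_histogram(bins = 40, fill = "#0072B2") +
    ggplot2::labs(x = "relative depth error (%)", y = "pixels") +
    ggplot2::theme_minimal()
}

#' Spike raster of the network output
#'
#' OUT spike trains (one row per pixel, row-major index) with the Sync time
#' marked: the classic raster view of the focus-detection circuit, where
#' depth is encoded in the OUT-to-Sync interval.
#'
#' @param rec An [run_network()] result with `record = "full"`.
#' @param max_pixels At most this many (first) pixels with spikes are shown.
#' @param path Optional PNG path; when given, the plot is also written there.
#' @return A ggplot object.
#' @export
plot_spike_raster <- function(rec, max_pixels = 200, path = NULL) {
  sp <- attr(rec, "out_spikes")
  if (is.null(sp) || nrow(sp) == 0) {
    abort("no spike record: run the network with record = \"full\".")
  }
  keep <- sort(unique(sp$pixel))
  keep <- keep[seq_len(min(length(keep), max_pixels))]
  df <- dplyr::filter(sp, .data$pixel %in% keep)
  sync_us <- unique(tibble::as_tibble(rec)$sync_us)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_us / 1e3,
                                         y = .data$pixel)) +
    ggplot2::geom_point(shape = "|", size = 2, colour = "#0072B2") +
    ggplot2::geom_vline(xintercept = sync_us / 1e3, colour = "#D55E00",
                        linetype = 2) +
    ggplot2::labs(x = "time (ms)", y = "pixel (OUT neuron)",
                  subtitle = "dashed: Sync") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, pl, width = 6, height = 4, dpi = 150)
  }
  pl
}
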
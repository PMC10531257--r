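#' Plot an MFR activity map
#'
#' @param object An `activity_map` matrix from [activity_map()].
#' @param ... Unused.
#' @return A ggplot raster of mean firing rate over the electrode grid.
#' @export
autoplot.activity_map <- function(object, ...) {
  df <- tibble::tibble(
    row = as.vector(row(object)) - 1L,
    col = as.vector(col(object)) - 1L,
    mfr = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = mfr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "MFR (spikes/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row",
                  title = "Mean firing rate activity map") +
    ggplot2::theme_minimal()
}

#' Raster plot of spike trains
#'
#' @param object A [spike_trains()] table.
#' @param ... Unused.
#' @return A ggplot raster: one horizontal lane per electrode (row-major
#'   electrode index), one point per spike.
#' @export
autoplot.spike_trains <- function(object, ...) {
  g <- train_grid(object)
  df <- tibble::as_tibble(object)
  df$electrode <- df$row * g$n_cols + df$col
  ggplot2::ggplot(df, ggplot2::aes(x = time_s, y = electrode)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "electrode (row-major index)",
                  title = "Spike raster") +
    ggplot2::theme_minimal()
}

#' Plot LFP event amplitudes over the grid
#'
#' @param object An `lfp_events` table.
#' @param ... Unused.
#' @return A ggplot of event peak times vs electrode, colored by
#'   amplitude, with invalid events hollow.
#' @export
autoplot.lfp_events <- function(object, ...) {
  g <- attr(object, "grid")
  df <- tibble::as_tibble(object)
  df$electrode <- df$row * g$n_cols + df$col
  df$validity <- ifelse(is.na(df$valid), "unchecked",
                        ifelse(df$valid, "valid", "invalid"))
  ggplot2::ggplot(df, ggplot2::aes(x = peak_time_s, y = electrode,
                                   color = amplitude_uv,
                                   shape = validity)) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(valid = 16, invalid = 1,
                                           unchecked = 18)) +
    ggplot2::scale_color_gradient2(name = "amplitude (uV)") +
    ggplot2::labs(x = "peak time (s)", y = "electrode (row-major index)",
                  title = "LFP events") +
    ggplot2::theme_minimal()
}

#' Plot a CSD frame with sinks blue and sources red
#'
#' @param csd A `csd_volume`.
#' @param time_s Time of the frame to show, seconds.
#' @return A ggplot raster; sinks (negative CSD) in blue, sources in red.
#' @export
plot_csd_frame <- function(csd, time_s) {
  fr <- sink_source_frames(csd, time_s)$frames[[1]]
  m <- fr$signed
  df <- tibble::tibble(row = as.vector(row(m)) - 1L,
                       col = as.vector(col(m)) - 1L,
                       csd = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = csd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "CSD (a.u.)", na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row",
                  title = sprintf("CSD frame at t = %.3f s", fr$time_s)) +
    ggplot2::theme_minimal()
}
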
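#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Space-time histogram plot of a filter trace
#'
#' Raster of the 50-bin horizontal-position histograms as a function of time,
#' faceted by layer and stimulus — the standard way to look at the internal
#' dynamics of the tracker (delayed source layer vs delay-compensated target
#' layer).
#'
#' @param object An `fle_trace`.
#' @param stimulus Stimuli to show.
#' @param layers Layers to show.
#' @param n_bins Histogram resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fle_trace
#' @export
autoplot.fle_trace <- function(object, stimulus = "dot",
                               layers = c("source", "target"),
                               n_bins = 50, ...) {
  tk <- frame_times(object$stim)
  df <- purrr::map_dfr(seq_len(object$n_frames), function(k) {
    purrr::map_dfr(stimulus, function(s) {
      purrr::map_dfr(layers, function(ly) {
        h <- position_histogram(get_ensemble(object, k, ly, s), n_bins)
        tibble::tibble(time = tk[k], stimulus = s, layer = ly,
                       x = h$mid, mass = h$mass)
      })
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$x,
                                   fill = .data$mass)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(stimulus ~ layer) +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::labs(x = "time (s)", y = "horizontal position",
                  fill = "posterior\nmass") +
    ggplot2::theme_minimal()
}

#' Lag-versus-value plot of a parameter sweep
#'
#' Mean flash-lag with +/- 1 SD error bars across trials per swept value.
#'
#' @param object An [fle_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fle_sweep
#' @export
autoplot.fle_sweep <- function(object, ...) {
  sm <- object |>
    dplyr::group_by(.data$variable, .data$value) |>
    dplyr::summarise(mean_lag = mean(.data$lag), sd_lag = stats::sd(.data$lag),
                     .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$value, y = .data$mean_lag)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_lag - .data$sd_lag,
      ymax = .data$mean_lag + .data$sd_lag)) +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "flash-lag (space units)") +
    ggplot2::theme_minimal()
}

#' Show one movie frame
#'
#' @param movie An [render_movie()] result.
#' @param frame Frame index.
#' @return A ggplot raster of the frame in stimulus coordinates.
#' @export
plot_frame <- function(movie, frame) {
  f <- movie$frames[, , frame]
  df <- expand.grid(x = pixel_centers(nrow(f)), y = pixel_centers(ncol(f)))
  df$I <- as.vector(f)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$I)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("frame %d (t = %.3f s)", frame,
                                  frame_times(movie$params)[frame])) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
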
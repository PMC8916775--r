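# ggplot2 views of the main result types.

#' @export
autoplot.csd_profile <- function(object, ...) {
  df <- tidy(object)
  yvar <- if (!is.null(object$depth_um)) "depth_um" else "channel"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data[[yvar]],
                                   fill = .data$csd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    {if (yvar == "channel") ggplot2::scale_y_reverse() else NULL} +
    ggplot2::labs(x = "time (ms)",
                  y = if (yvar == "depth_um") "depth (µm)" else "channel",
                  fill = if (object$normalization == "raw") "CSD (A/m³)"
                         else "CSD (norm.)",
                  title = "CSD depth profile (sink-positive)")
}

#' @export
autoplot.pta_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_ms, y = .data$channel,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "lag (ms)", y = "channel", fill = "LFPbp (µV)",
                  title = sprintf("Phase-triggered average, ref channel %d, %g-%g Hz",
                                  object$reference_channel, object$band[1],
                                  object$band[2]))
}

#' @export
autoplot.gc_graph <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$source), y = factor(.data$target),
                               fill = .data$net, alpha = .data$rgt_pass)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                name = "RGT pass") +
    ggplot2::facet_wrap(~ .data$band) +
    ggplot2::labs(x = "source channel", y = "target channel",
                  fill = "net GC (nats)",
                  title = "Band-integrated net Granger causality")
}

#' @export
autoplot.isp <- function(object, ...) {
  df <- tibble(
    freq_hz = rep(object$freq_hz, times = ncol(object$z)),
    time_ms = rep(object$time_ms, each = nrow(object$z)),
    z = as.vector(object$z))
  ggplot2::ggplot(dplyr::filter(df, .data$freq_hz <= 100),
                  ggplot2::aes(x = .data$time_ms, y = .data$freq_hz,
                               fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "time (ms)", y = "frequency (Hz)", fill = "iSP (z)",
                  title = "Induced spectral power")
}

#' Size-tuning curves from a size-tuning summary
#'
#' @param summary tibble from [summarize_size_tuning()].
#' @param response which response to plot (default `"muae_z"`).
#' @return a ggplot.
#' @export
plot_size_tuning <- function(summary, response = "muae_z") {
  df <- dplyr::filter(summary, .data$response == !!response)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter_deg, y = .data$mean,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "grating diameter (deg)", y = response,
                  title = "Size tuning by laminar compartment")
}
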
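#' Plot an EMG recording
#'
#' Channel voltage traces over time, one facet per channel.
#'
#' @param object an [emg_recording()].
#' @param max_samples thin the trace to at most this many samples per
#'   channel (plotting only).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.emg_recording <- function(object, max_samples = 20000, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  df$time <- attr(object, "t0") + (seq_len(nrow(df)) - 1) /
    sampling_rate(object)
  if (nrow(df) > max_samples) {
    df <- df[seq(1, nrow(df), length.out = max_samples), ]
  }
  long <- tidyr::pivot_longer(df, -"time",
                              names_to = "channel", values_to = "voltage")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "voltage (V)")
}

#' Plot a spectral feature stream
#'
#' Feature amplitude over time as a channel-by-frequency heat map: the
#' per-motion channel activation patterns the classifier learns are
#' directly visible.
#'
#' @param features a feature tibble from [extract_features()].
#' @return a ggplot.
#' @export
plot_features <- function(features) {
  long <- tidyr::pivot_longer(
    features, dplyr::all_of(feature_cols(features)),
    names_to = "feature", values_to = "amplitude"
  )
  long$feature <- factor(long$feature, levels = feature_cols(features))
  ggplot2::ggplot(long, ggplot2::aes(.data$frame_time, .data$feature,
                                     fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "amplitude")
}

#' Plot the training loss trace of a fitted classifier
#'
#' @param object an `emg_ann`.
#' @param ... unused.
#' @return a ggplot of sum-of-squared-error loss per epoch.
#' @export
autoplot.emg_ann <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_trace),
                       loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "sum-of-squared-error loss")
}

#' Plot an evaluation report's confusion matrix
#'
#' @param object an `emg_eval`.
#' @param ... unused.
#' @return a ggplot heat map, rows = true motion, columns = predicted.
#' @export
autoplot.emg_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$predicted),
                                   factor(.data$true), fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted motion", y = "true motion", fill = "frames")
}
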
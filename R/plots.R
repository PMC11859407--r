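#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_path geom_tile
#'   geom_text facet_wrap labs theme_minimal coord_equal scale_fill_gradient
#' @export
ggplot2::autoplot

#' Plot a multi-channel sEMG recording
#'
#' Channels are faceted over time with the intent label shown as a shaded
#' step trace.
#'
#' @param object An `emg_recording`.
#' @param channels Channels to show (default: first 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emg_recording <- function(object, channels = NULL, ...) {
  channels <- channels %||% utils::head(object$channels, 4)
  df <- tibble::as_tibble(as.data.frame(object$samples[, channels, drop = FALSE]))
  df$time <- (seq_len(nrow(df)) - 1) / object$sample_rate
  df$label <- object$labels
  long <- tidyr::pivot_longer(df, dplyr::all_of(channels),
                              names_to = "channel", values_to = "mV")
  ggplot(long, aes(x = .data$time, y = .data$mV)) +
    geom_line(linewidth = 0.2) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time [s]", y = "amplitude [mV]") +
    theme_minimal()
}

#' Plot a trajectory over its standard path
#'
#' @param object A `trajectory_record`.
#' @param path Optional [path_spec()] drawn underneath.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_record <- function(object, path = NULL, ...) {
  p <- ggplot(object, aes(x = .data$x, y = .data$y))
  if (!is.null(path)) {
    wp <- tibble::tibble(x = path$waypoints[, 1], y = path$waypoints[, 2])
    p <- p + geom_path(data = wp, colour = "red", linetype = "dashed")
  }
  p + geom_path(colour = "grey30") +
    coord_equal() +
    labs(x = "x [m]", y = "y [m]") +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object An `intent_confusion` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intent_confusion <- function(object, ...) {
  df <- tidy.intent_confusion(object)
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted intent", y = "true intent") +
    theme_minimal()
}

#' Plot training curves of a trained model
#'
#' @param model A trained `intent_model`.
#' @return A ggplot object with loss and accuracy per epoch.
#' @export
plot_training_history <- function(model) {
  h <- tidy.intent_model(model)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric",
                              values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    theme_minimal()
}

#' Plot a hyperparameter-search trace
#'
#' Accuracy per trial with the running best overlaid.
#'
#' @param search A `hyper_search`.
#' @return A ggplot object.
#' @export
plot_search_trace <- function(search) {
  df <- dplyr::mutate(search$trials, best = cummax(.data$accuracy))
  ggplot(df, aes(x = .data$trial)) +
    geom_line(aes(y = .data$best), colour = "steelblue") +
    ggplot2::geom_point(aes(y = .data$accuracy), size = 1) +
    labs(x = "trial", y = "validation accuracy") +
    theme_minimal()
}
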
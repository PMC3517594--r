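#' Plot helpers
#'
#' Quick ggplot2 views of the package's main objects: the modulation code
#' and its per-target shifts, templates, session accuracy over trials, and
#' the average error-minus-correct feedback wave.
#'
#' @name plots
NULL

#' Plot the modulation sequence of the first few targets
#'
#' @param code A [binary_code()].
#' @param layout A [target_layout()].
#' @param targets Target indices to display.
#' @return A ggplot object.
#' @export
plot_code <- function(code, layout = target_layout(), targets = 0:4) {
  df <- dplyr::bind_rows(lapply(targets, function(k) {
    tibble::tibble(target = factor(k), bit_index = seq_along(code$bits),
                   bit = shift_code(code, k, layout)$bits)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bit_index, y = .data$bit)) +
    ggplot2::geom_step() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$target)) +
    ggplot2::labs(x = "bit", y = NULL,
                  title = "Modulation sequence per target (circular shifts)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a template set's base template
#'
#' @param object A `template_set`.
#' @param fs Sampling rate used for the time axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.template_set <- function(object, fs = 600, ...) {
  df <- tibble::tibble(time_s = (seq_along(object$base_template) - 1) / fs,
                       amplitude = object$base_template)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "filtered amplitude",
                  title = "Base template (target 0 frame)") +
    ggplot2::theme_minimal()
}

#' Rolling classification accuracy over a session
#'
#' @param log A session-log tibble from [run_experiment()].
#' @param window Rolling window in trials.
#' @return A ggplot object.
#' @export
plot_session_accuracy <- function(log, window = 16) {
  roll <- stats::filter(as.numeric(log$correct), rep(1 / window, window),
                        sides = 1)
  df <- tibble::tibble(trial = log$trial, accuracy = as.numeric(roll),
                       phase = log$phase)
  ggplot2::ggplot(stats::na.omit(df),
                  ggplot2::aes(.data$trial, .data$accuracy,
                               colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "trial", y = sprintf("accuracy (%d-trial window)",
                                           window)) +
    ggplot2::theme_minimal()
}

#' Average error-minus-correct feedback wave at one channel
#'
#' @param error_epochs,correct_epochs Lists of [feedback_epoch()] objects.
#' @param channel Channel label.
#' @return A ggplot object.
#' @export
plot_errp_difference <- function(error_epochs, correct_epochs,
                                 channel = "Cz") {
  avg <- function(epochs) {
    Reduce(`+`, lapply(epochs, function(e) e$data[channel, ])) /
      length(epochs)
  }
  fs <- error_epochs[[1]]$fs
  d <- avg(error_epochs) - avg(correct_epochs)
  df <- tibble::tibble(time_s = (seq_along(d) - 1) / fs, amplitude = d)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0.31, 0.42), linetype = "dashed") +
    ggplot2::labs(x = "time after feedback (s)", y = "difference (uV)",
                  title = sprintf("Error minus correct at %s", channel)) +
    ggplot2::theme_minimal()
}
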
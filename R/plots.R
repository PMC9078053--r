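#' Plot response-error histograms with a model overlay
#'
#' Data proportions as points/bars per folded condition, with the model's
#' mean curve and 95% simulation envelope (from [model_envelope()]) overlaid
#' when a fit is supplied.
#'
#' @param data Histogram tibble from [matching_histograms()].
#' @param fit Optional `crowding_fit`; its envelope is drawn as a ribbon and
#'   mean line.
#' @param envelope Optional precomputed [model_envelope()] tibble (overrides
#'   `fit`).
#' @param n_iter,trials_per_iter Passed to [model_envelope()] when `fit` is
#'   given.
#' @return A ggplot object.
#' @export
plot_error_histograms <- function(data, fit = NULL, envelope = NULL,
                                  n_iter = 1000, trials_per_iter = 1000) {
  if (is.null(envelope) && !is.null(fit)) {
    envelope <- model_envelope(fit, n_iter = n_iter,
                               trials_per_iter = trials_per_iter)
  }
  lvls <- c("unflanked", "f30", "f90")
  data$condition <- factor(data$condition, levels = lvls)
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$bin_center,
                                    y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey70", width = 9) +
    ggplot2::facet_wrap(~condition, nrow = 1) +
    ggplot2::labs(x = "Response error (deg)", y = "Proportion of trials") +
    ggplot2::theme_minimal()
  if (!is.null(envelope)) {
    envelope$condition <- factor(envelope$condition, levels = lvls)
    p <- p +
      ggplot2::geom_ribbon(
        data = envelope,
        ggplot2::aes(x = .data$bin_center, ymin = .data$lo, ymax = .data$hi),
        inherit.aes = FALSE, alpha = 0.3) +
      ggplot2::geom_line(
        data = envelope,
        ggplot2::aes(x = .data$bin_center, y = .data$mean),
        inherit.aes = FALSE, linewidth = 0.8)
  }
  p
}

#' @rdname plot_error_histograms
#' @param object A `crowding_fit`.
#' @param data_hist Histogram tibble the fit was computed on.
#' @param ... Passed to [plot_error_histograms()].
#' @method autoplot crowding_fit
#' @export
autoplot.crowding_fit <- function(object, data_hist, ...) {
  plot_error_histograms(data_hist, fit = object, ...)
}

#' Plot a population response
#'
#' @param object A [population_response()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot population_response
#' @export
autoplot.population_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$channel_deg,
                                       y = .data$activity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Channel orientation (deg)", y = "Activity") +
    ggplot2::theme_minimal()
}

#' Plot a staircase run
#'
#' Gap size per trial (log scale), colored by trial type, with the running
#' threshold estimate overlaid.
#'
#' @param object A `quest_run` from [tailored_quest_run()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quest_run
#' @export
autoplot.quest_run <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$trial, y = .data$gap,
                                  color = .data$type)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate),
                       color = "black", linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Trial", y = "Gap size (arcmin)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
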
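#' Plot a reaching run
#'
#' Per-trial Euclidean error with a moving-average overlay, the standard
#' learning-curve view of the reaching task.
#'
#' @param object A `reaching_run`.
#' @param window Moving-average window, trials.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reaching_run
#' @export
autoplot.reaching_run <- function(object, window = 10, ...) {
  tr <- object$trials
  window <- min(window, nrow(tr))
  tr$ma <- as.numeric(stats::filter(tr$error, rep(1 / window, window), sides = 1))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$error), alpha = 0.25, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ma), colour = "#d95f02", linewidth = 0.8,
                       na.rm = TRUE) +
    ggplot2::labs(x = "trial", y = "goal distance (workspace units)",
                  title = sprintf("Reaching (%s, %d goals)", object$mode,
                                  nrow(object$goals))) +
    ggplot2::theme_minimal()
}

#' Plot an adaptation run
#'
#' Signed task angular error per trial with the phase boundaries marked;
#' the classic visuomotor-rotation figure (error jump at onset, drift or
#' decay during the perturbation, aftereffect at offset).
#'
#' @param object An `adaptation_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot adaptation_run
#' @export
autoplot.adaptation_run <- function(object, ...) {
  tr <- object$trials
  bounds <- cumsum(rle(tr$phase)$lengths)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trial, y = .data$angular_error)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = utils::head(bounds, -1L) + 0.5,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "trial", y = "angular error (deg)",
                  title = paste("Visuomotor adaptation:", object$schedule$condition),
                  subtitle = if (object$ablate_cerebellum) "cerebellum ablated") +
    ggplot2::theme_minimal()
}

#' Plot a variability sweep
#'
#' Adaptation speed (trials to half error) against perturbation amplitude
#' and frequency.
#'
#' @param object A `variability_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot variability_sweep
#' @export
autoplot.variability_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$value), y = .data$speed)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(ggplot2::vars(.data$factor), scales = "free_x") +
    ggplot2::labs(x = "perturbation parameter value",
                  y = "trials to half error") +
    ggplot2::theme_minimal()
}

#' Plot the act-and-sense pretraining curve
#'
#' Goal-to-outcome distance per pretraining trial with a moving average:
#' as the outcome-action map forms, intended outcomes become associated
#' with actions that reach them.
#'
#' @param model A pretrained [motor_model()].
#' @param window Moving-average window, trials.
#' @return A ggplot.
#' @export
plot_pretraining <- function(model, window = 10) {
  stopifnot(!is.null(model$pretraining))
  tr <- model$pretraining
  window <- min(window, nrow(tr))
  tr$ma <- as.numeric(stats::filter(tr$distance, rep(1 / window, window), sides = 1))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$distance), alpha = 0.3, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ma), colour = "#1b9e77",
                       linewidth = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "pretraining trial", y = "goal-outcome distance",
                  title = "Act-and-sense basal-ganglia pretraining") +
    ggplot2::theme_minimal()
}
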
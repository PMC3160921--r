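#' Plot an experiment
#'
#' Two views of a [run_validation_experiment()] result:
#'
#' * `type = "kappa_error"`: per-draw Cohen's kappa against total absolute
#'   CSMF error, one panel per method — the picture showing that individual
#'   cause assignment quality and CSMF estimation quality are nearly
#'   unrelated, so kappa must not be read as a CSMF-accuracy measure.
#' * `type = "csmf_scatter"`: estimated against true CSMF per cause and
#'   method, with the identity line; the cloud's intercept, slope and spread
#'   are the regression diagnostics of [experiment_regressions()].
#'
#' @param object A `va_experiment`.
#' @param type `"kappa_error"` or `"csmf_scatter"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.va_experiment <- function(object,
                                   type = c("kappa_error", "csmf_scatter"),
                                   ...) {
  type <- match.arg(type)
  if (type == "kappa_error") {
    ggplot2::ggplot(object$overall,
                    ggplot2::aes(x = .data$kappa,
                                 y = .data$total_absolute_error)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::facet_wrap(~method) +
      ggplot2::labs(x = "Cohen's kappa", y = "Total absolute CSMF error") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$cause_results,
                    ggplot2::aes(x = .data$true_csmf,
                                 y = .data$predicted_csmf)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.8) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::facet_grid(method ~ cause) +
      ggplot2::labs(x = "True CSMF", y = "Estimated CSMF") +
      ggplot2::theme_minimal()
  }
}

#' Running-median stabilization curve
#'
#' The running median of a resampled metric as a function of the number of
#' draws: the visual check that enough compositions have been drawn for the
#' reported median to be stable.
#'
#' @param object A `va_resampling` object from [median_over_draws()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.va_resampling <- function(object, ...) {
  ggplot2::ggplot(object$running_median,
                  ggplot2::aes(x = .data$draw, y = .data$median)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Draws", y = "Running median") +
    ggplot2::theme_minimal()
}
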
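#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted calibration curve
#'
#' Calibration points with the fitted `y = a*log10(x) + b` curve on a
#' log-scaled amplitude axis, mirroring how bench calibration results are
#' conventionally displayed.
#'
#' @param object A [fit_log_calibration()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calibration_fit
#' @export
autoplot.calibration_fit <- function(object, ...) {
  cal <- object$calibration
  rng <- range(object$data$amplitude)
  grid <- tibble::tibble(
    amplitude = 10^seq(log10(rng[1]), log10(rng[2]), length.out = 100)
  )
  grid$fitted_db <- amplitude_to_db(grid$amplitude, cal)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = amplitude, y = reference_db)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = fitted_db), colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "device amplitude (log scale)", y = "reference level [dB(C)]",
      title = cal$model_name,
      subtitle = sprintf("y = %.4f log10(x) + %.4f,  R² = %.4f",
                         cal$slope, cal$intercept, cal$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an amplitude measurement series
#'
#' Per-sample amplitudes over the 15 s measurement window, with the
#' discarded startup samples marked.
#'
#' @param object An [amplitude_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amplitude_series
#' @export
autoplot.amplitude_series <- function(object, ...) {
  df <- tibble::tibble(
    time_s = (seq_along(object$samples) - 1) * 0.5,
    amplitude = object$samples,
    retained = seq_along(object$samples) > object$n_discard
  )
  ggplot2::ggplot(df, ggplot2::aes(time_s, amplitude, colour = retained)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey70") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "firebrick"),
      labels = c(`TRUE` = "retained", `FALSE` = "discarded")
    ) +
    ggplot2::labs(x = "time [s]", y = "recorder amplitude", colour = NULL) +
    ggplot2::theme_minimal()
}
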
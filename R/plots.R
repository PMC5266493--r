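#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum estimate with an optional power-law fit
#'
#' Log-log spectrum with the fitted aperiodic background overlaid; the
#' band-limited excess above the red fit line is what the oscillation
#' test quantifies.
#'
#' @param object A `spectrum_estimate`.
#' @param fit Optional `power_law_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectrum_estimate <- function(object, fit = NULL, ...) {
  df <- tidy(object)
  df <- df[df$freq > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(power ~ (mu * V^2 / Hz)))
  if (!is.null(fit)) {
    fd <- tibble::tibble(freq = fit$freqs, power = fit$fitted_values)
    fd <- fd[!is.na(fd$power) & fd$freq >= fit$fit_band[1] &
               fd$freq <= fit$fit_band[2], ]
    p <- p + ggplot2::geom_line(data = fd, colour = "red")
  }
  p
}

#' Plot a hypnogram
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot object (stage vs time step plot).
#' @export
autoplot.hypnogram <- function(object, ...) {
  len <- epoch_length_s(object)
  df <- tibble::tibble(
    time_min = (object$epoch - 1) * len / 60,
    stage = factor(as.character(object$stage),
                   levels = rev(c("W", "REM", "N1", "N2", "N3", "other")))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$stage,
                                   group = 1)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = NULL)
}

#' Plot a cross-covariance function
#'
#' @param object A `crosscov_result`.
#' @param window_ms Shaded asymmetry window half-width (ms).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crosscov_result <- function(object, window_ms = 100, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_ms, y = .data$ccov)) +
    ggplot2::annotate("rect", xmin = 0, xmax = window_ms, ymin = -Inf,
                      ymax = Inf, alpha = 0.08, fill = "blue") +
    ggplot2::annotate("rect", xmin = -window_ms, xmax = 0, ymin = -Inf,
                      ymax = Inf, alpha = 0.08, fill = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "lag (ms)", y = "envelope cross-covariance")
}

#' Plot a burst occupancy raster
#'
#' @param raster Matrix from [burst_raster()].
#' @return A ggplot object (derivation x time tiles).
#' @export
plot_burst_raster <- function(raster) {
  bins <- attr(raster, "bin_start_s")
  df <- tidyr::expand_grid(
    derivation = factor(rownames(raster), levels = rev(rownames(raster))),
    bin = seq_len(ncol(raster))
  )
  df$occupied <- as.vector(t(raster))
  df$time_s <- bins[df$bin]
  df <- df[df$occupied, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$derivation)) +
    ggplot2::geom_point(colour = "blue", size = 0.8) +
    ggplot2::labs(x = "time (s)", y = NULL)
}
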
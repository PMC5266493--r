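# Lead/lag analysis of band-power envelopes between region pairs.
#
# Sign convention (pinned by a dedicated test): window_crosscov(d, a) with
# d = leading-region (DLPFC) envelope and a = following-region (ACC)
# envelope computes CC(tau) = mean_t (d(t) - dbar)(a(t + tau) - abar), so
# a peak at tau > 0 means the first argument (DLPFC) leads.

#' Mean envelope power per analysis window
#'
#' @param envelope Envelope vector (from [band_envelope()]).
#' @param rate Sampling rate (Hz).
#' @param windows Window table (from [window_2s()]).
#' @return Tibble with `window_index` and `power` (mean squared envelope).
#' @export
window_envelope_power <- function(envelope, rate, windows) {
  if (nrow(windows) == 0) {
    return(tibble::tibble(window_index = integer(), power = numeric()))
  }
  ns <- round((windows$end_s[1] - windows$start_s[1]) * rate)
  p <- vapply(seq_len(nrow(windows)), function(i) {
    i0 <- round(windows$start_s[i] * rate)
    mean(envelope[(i0 + 1):(i0 + ns)]^2)
  }, numeric(1))
  tibble::tibble(window_index = seq_len(nrow(windows)), power = p)
}

#' Windows where both electrodes sit in their top power quartile
#'
#' Indices of windows in which both per-window powers reach the 75th
#' percentile (linear-interpolation percentile) of their own series; the
#' quartile is computed with respect to the REM episode the powers come
#' from.
#'
#' @param powers_a,powers_b Numeric vectors of per-window power (equal
#'   length, at least 8 windows).
#' @return Integer window indices (possibly empty; callers should skip a
#'   pair whose intersection is empty).
#' @export
select_joint_top_quartile <- function(powers_a, powers_b) {
  stopifnot(length(powers_a) == length(powers_b), length(powers_a) >= 8)
  qa <- stats::quantile(powers_a, 0.75, names = FALSE)
  qb <- stats::quantile(powers_b, 0.75, names = FALSE)
  which(powers_a >= qa & powers_b >= qb)
}

#' Cross-covariance of two envelope windows
#'
#' Biased (1/N) demeaned cross-covariance
#' `CC(tau) = (1/N) * sum_t (d(t) - dbar)(a(t + tau) - abar)` on the
#' sample lag grid; a peak at positive `tau` means the first argument
#' leads.
#'
#' @param env_d,env_a Envelope segments of equal length (leading-candidate
#'   first).
#' @param rate Sampling rate (Hz).
#' @param max_lag_ms Maximum lag magnitude (ms); must be below half the
#'   window length.
#' @return Tibble with `lag_ms` and `ccov`. A zero-variance window yields
#'   an all-zero function flagged by the `degenerate` attribute.
#' @export
window_crosscov <- function(env_d, env_a, rate, max_lag_ms = 250) {
  stopifnot(length(env_d) == length(env_a))
  max_lag <- round(max_lag_ms / 1000 * rate)
  if (max_lag >= length(env_d) / 2) {
    stop("max_lag_ms must be below half the window length", call. = FALSE)
  }
  lags <- -max_lag:max_lag
  if (stats::sd(env_d) == 0 || stats::sd(env_a) == 0) {
    out <- tibble::tibble(lag_ms = lags / rate * 1000,
                          ccov = numeric(length(lags)))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # ccf(x, y)[k] estimates mean (x(t+k) - xbar)(y(t) - ybar) with 1/N
  # scaling, so CC(tau) = ccf(env_a, env_d)[tau]
  cc <- stats::ccf(env_a, env_d, lag.max = max_lag, type = "covariance",
                   demean = TRUE, plot = FALSE)
  out <- tibble::tibble(lag_ms = lags / rate * 1000, ccov = as.numeric(cc$acf))
  attr(out, "degenerate") <- FALSE
  out
}

#' Average cross-covariance for one electrode pair
#'
#' Computes the per-window cross-covariance for the selected windows of an
#' episode and averages pointwise.
#'
#' With `lag_extended = TRUE` (the default) the lagged channel is read
#' from the episode envelope continuing past the window edges, so every
#' lag sees the full window's worth of products. The within-window
#' estimator truncates the overlap, which attenuates the function by the
#' triangular factor `1 - |tau|/N` and biases the apex of broad envelope
#' cross-covariances toward zero lag; reading past the edges removes that
#' distortion. Windows whose lag extension would leave the episode are
#' skipped.
#'
#' @param env_d,env_a Full-episode envelopes (leading-candidate first).
#' @param rate Sampling rate (Hz).
#' @param windows Window table from [window_2s()].
#' @param use Window indices to include (e.g. from
#'   [select_joint_top_quartile()]); default all.
#' @param max_lag_ms Maximum lag (ms).
#' @param lag_extended Read the lagged channel past window edges (default
#'   `TRUE`); `FALSE` averages plain [window_crosscov()] functions.
#' @param pair_id,band Identifiers carried into the result.
#' @return Object of class `crosscov_result`: list with `lag_ms`, `ccov`,
#'   `n_windows_used`, `pair_id`, `band`.
#' @export
pair_crosscov <- function(env_d, env_a, rate, windows,
                          use = seq_len(nrow(windows)), max_lag_ms = 250,
                          lag_extended = TRUE,
                          pair_id = NA_character_, band = NA_character_) {
  stopifnot(length(use) >= 1)
  ns <- round((windows$end_s[1] - windows$start_s[1]) * rate)
  max_lag <- round(max_lag_ms / 1000 * rate)
  lags <- -max_lag:max_lag
  acc <- numeric(length(lags))
  n_used <- 0L
  for (i in use) {
    i0 <- round(windows$start_s[i] * rate)
    if (lag_extended) {
      if (i0 - max_lag < 0 || i0 + ns + max_lag > length(env_a)) next
      d_c <- env_d[(i0 + 1):(i0 + ns)]
      d_c <- d_c - mean(d_c)
      a_ext <- env_a[(i0 + 1 - max_lag):(i0 + ns + max_lag)]
      # cross-products for all lags in one FFT convolution:
      # conv[k] = sum_t a_ext[t] * d_c[t - k + ns] (rev kernel)
      # d_c is zero-mean, so demeaning the shifted segment is a no-op in
      # the product sum
      cv <- stats::convolve(a_ext, d_c, type = "open")
      prod_sums <- cv[ns + max_lag + lags]
      acc <- acc + prod_sums / ns
      n_used <- n_used + 1L
    } else {
      sel <- (i0 + 1):(i0 + ns)
      cc <- window_crosscov(env_d[sel], env_a[sel], rate, max_lag_ms)
      acc <- acc + cc$ccov
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("no usable windows for the lag range", call. = FALSE)
  structure(
    list(
      lag_ms = lags / rate * 1000,
      ccov = acc / n_used,
      n_windows_used = n_used,
      pair_id = pair_id,
      band = if (inherits(band, "band_def")) band$name else band
    ),
    class = "crosscov_result"
  )
}

#' Average cross-covariance functions across pairs
#'
#' Pointwise arithmetic mean of pair-level functions on a shared lag grid
#' (the grand-average function of a cohort). Callers restrict the input to
#' pairs with significant band coherence.
#'
#' @param results List of `crosscov_result` objects.
#' @return A `crosscov_result` with `pair_id = "grand_average"`.
#' @export
average_crosscov <- function(results) {
  if (!length(results)) stop("no eligible pairs to average", call. = FALSE)
  lag_ms <- results[[1]]$lag_ms
  stopifnot(all(vapply(results, function(r) {
    length(r$lag_ms) == length(lag_ms) && all(r$lag_ms == lag_ms)
  }, logical(1))))
  ccov <- rowMeans(vapply(results, function(r) r$ccov, numeric(length(lag_ms))))
  structure(
    list(
      lag_ms = lag_ms, ccov = ccov,
      n_windows_used = sum(vapply(results, function(r) r$n_windows_used,
                                  numeric(1))),
      pair_id = "grand_average",
      band = results[[1]]$band
    ),
    class = "crosscov_result"
  )
}

#' @export
print.crosscov_result <- function(x, ...) {
  cat(sprintf(
    "<crosscov_result> %s (%s): peak lag %+g ms over %d window(s)\n",
    x$pair_id, x$band, peak_lag(x), x$n_windows_used
  ))
  invisible(x)
}

#' Tidy a cross-covariance result
#' @param x A `crosscov_result`.
#' @param ... Unused.
#' @return Tibble with `pair_id`, `band`, `lag_ms`, `ccov`.
#' @export
tidy.crosscov_result <- function(x, ...) {
  tibble::tibble(pair_id = x$pair_id, band = x$band,
                 lag_ms = x$lag_ms, ccov = x$ccov)
}

#' Lag of the cross-covariance maximum
#'
#' Lag (ms) at the global maximum of the function; among tied maxima the
#' lag closest to zero wins. An all-equal function returns 0 with a
#' `degenerate` attribute.
#'
#' @param result A `crosscov_result`.
#' @return Peak lag in ms.
#' @export
peak_lag <- function(result) {
  cc <- result$ccov
  if (max(cc) == min(cc)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  at_max <- which(cc == max(cc))
  result$lag_ms[at_max[which.min(abs(result$lag_ms[at_max]))]]
}

#' Lead/lag asymmetry of a cross-covariance function
#'
#' Signed area `A = int_0^w CC - int_-w^0 CC` by the trapezoidal rule on
#' the lag grid (the zero-lag sample contributes half to each side).
#' Positive `A` means the first-argument region precedes.
#'
#' @param result A `crosscov_result` whose lag grid covers `+/- window_ms`.
#' @param window_ms Half-width of the asymmetry window (ms).
#' @return Signed area (envelope-power units^2 x ms).
#' @export
asymmetry_index <- function(result, window_ms = 100) {
  lg <- result$lag_ms
  if (min(lg) > -window_ms || max(lg) < window_ms) {
    stop("lag grid does not cover +/-", window_ms, " ms", call. = FALSE)
  }
  pos <- lg >= 0 & lg <= window_ms
  neg <- lg <= 0 & lg >= -window_ms
  trapz(lg[pos], result$ccov[pos]) - trapz(lg[neg], result$ccov[neg])
}

#' Count pairs with positive asymmetry
#'
#' Cohort helper for asymmetry histograms: the number (and fraction) of
#' pairs whose asymmetry index is positive.
#'
#' @param results List of `crosscov_result` objects.
#' @param window_ms Asymmetry window half-width (ms).
#' @return Tibble with `n_pairs`, `n_positive`, `fraction_positive`.
#' @export
asymmetry_cohort <- function(results, window_ms = 100) {
  a <- vapply(results, asymmetry_index, numeric(1), window_ms = window_ms)
  tibble::tibble(
    n_pairs = length(a),
    n_positive = sum(a > 0),
    fraction_positive = mean(a > 0)
  )
}
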
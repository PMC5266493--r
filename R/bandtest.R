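#' Divide REM episodes into fixed-length analysis windows
#'
#' Non-overlapping, contiguous windows from each episode's start; any
#' trailing remainder shorter than `window_s` is discarded, and windows
#' never span episodes.
#'
#' @param episodes Tibble of episodes with `start_s`, `end_s` (from
#'   [select_rem_episodes()]).
#' @param window_s Window length in seconds.
#' @return Tibble with `episode`, `window` (1-based within episode),
#'   `start_s`, `end_s`.
#' @export
window_rem <- function(episodes, window_s = 10) {
  purrr::map_dfr(seq_len(nrow(episodes)), function(i) {
    k <- floor((episodes$end_s[i] - episodes$start_s[i]) / window_s)
    if (k < 1) return(NULL)
    tibble::tibble(
      episode = i,
      window = seq_len(k),
      start_s = episodes$start_s[i] + (seq_len(k) - 1) * window_s,
      end_s = episodes$start_s[i] + seq_len(k) * window_s
    )
  })
}

# slice a signal vector into a samples x windows matrix
signal_windows <- function(x, rate, windows) {
  ns <- round((windows$end_s[1] - windows$start_s[1]) * rate)
  sapply(seq_len(nrow(windows)), function(i) {
    i0 <- round(windows$start_s[i] * rate)
    x[(i0 + 1):(i0 + ns)]
  })
}

#' Band significance test of spectra against their power-law fits
#'
#' The oscillation-detection test: for each analysis window the band means
#' of the spectrum estimate and of its robust power-law fit form a matched
#' pair; a paired two-sided t-test across windows decides whether band
#' power exceeds the aperiodic background. Significance is Bonferroni
#' corrected for the number of electrodes tested simultaneously
#' (`p_raw < alpha / n_electrodes`). The band peak frequency is the
#' frequency of maximum mean excess (mean spectrum minus mean fit) inside
#' the band, reported only for significant electrodes.
#'
#' @param spectra List of `spectrum_estimate` objects (the electrode's
#'   windows).
#' @param fits Matched list of `power_law_fit` objects.
#' @param band Band (see [as_band()]).
#' @param n_electrodes Bonferroni divisor.
#' @param alpha Family-wise significance level.
#' @param electrode_id Identifier carried into the result.
#' @return One-row tibble: `electrode_id`, `band`, `t_stat`, `p_raw`,
#'   `p_bonferroni`, `significant`, `peak_freq`, `n_windows`, `degenerate`.
#' @export
band_significance_test <- function(spectra, fits, band, n_electrodes = 1,
                                   alpha = 0.05,
                                   electrode_id = NA_character_) {
  band <- as_band(band)
  stopifnot(length(spectra) == length(fits), length(spectra) >= 2)
  s_bar <- vapply(spectra, band_mean, numeric(1), band = band)
  r_bar <- vapply(fits, band_mean, numeric(1), band = band)
  d <- s_bar - r_bar
  degenerate <- stats::sd(d) == 0
  if (degenerate && abs(mean(d)) <= 1e-10 * max(abs(s_bar), 1e-300)) {
    t_stat <- 0
    p_raw <- 1
  } else if (degenerate) {
    t_stat <- NA_real_
    p_raw <- NA_real_
  } else {
    tt <- stats::t.test(d)
    t_stat <- unname(tt$statistic)
    p_raw <- tt$p.value
  }
  significant <- !is.na(p_raw) && p_raw < alpha / n_electrodes
  peak_freq <- NA_real_
  if (significant) {
    freqs <- spectra[[1]]$freqs
    sel <- which(freqs >= band$f_lo & freqs <= band$f_hi)
    excess <- rowMeans(vapply(spectra, function(s) s$power[sel],
                              numeric(length(sel)))) -
      rowMeans(vapply(fits, function(f) f$fitted_values[sel],
                      numeric(length(sel))))
    peak_freq <- freqs[sel][which.max(excess)]
  }
  tibble::tibble(
    electrode_id = electrode_id,
    band = band$name,
    t_stat = t_stat,
    p_raw = p_raw,
    p_bonferroni = if (is.na(p_raw)) NA_real_ else min(1, p_raw * n_electrodes),
    significant = significant,
    peak_freq = peak_freq,
    n_windows = length(spectra),
    degenerate = degenerate
  )
}

#' Windowed spectra, power-law fits and band tests for one channel
#'
#' Convenience wrapper running the full oscillation-detection chain for a
#' single signal: slice into windows, estimate a multitaper spectrum per
#' window, fit the power-law background per window, then run
#' [band_significance_test()] for each requested band.
#'
#' @param x Signal vector (uV).
#' @param rate Sampling rate (Hz).
#' @param windows Window table from [window_rem()].
#' @param bands List (or character vector) of bands to test.
#' @param n_electrodes,alpha Passed to [band_significance_test()].
#' @param time_halfbandwidth,n_tapers Multitaper parameters.
#' @param fit_band,exclude Power-law fit range and mains-guard exclusion.
#' @param electrode_id Identifier carried into results.
#' @return Tibble with one row per band.
#' @export
test_band_power <- function(x, rate, windows, bands = c("theta", "beta"),
                            n_electrodes = 1, alpha = 0.05,
                            time_halfbandwidth = 4, n_tapers = 7,
                            fit_band = c(2, 50), exclude = c(57.5, 62.5),
                            electrode_id = NA_character_) {
  wm <- signal_windows(x, rate, windows)
  spectra <- lapply(seq_len(ncol(wm)), function(j) {
    multitaper_spectrum(wm[, j], rate, time_halfbandwidth, n_tapers,
                        electrode_id = electrode_id, window_id = j)
  })
  fits <- lapply(spectra, fit_power_law, fit_band = fit_band, exclude = exclude)
  purrr::map_dfr(bands, function(bd) {
    band_significance_test(spectra, fits, bd, n_electrodes, alpha, electrode_id)
  })
}

#' Summarise band-test results over a region
#'
#' @param results Tibble of [band_significance_test()] rows for one region.
#' @return Tibble per band: `n`, `n_significant`, `fraction_significant`,
#'   and the median peak frequency among significant electrodes (`NA`
#'   when none are significant).
#' @export
summarize_region <- function(results) {
  stopifnot(nrow(results) >= 1)
  dplyr::summarise(
    dplyr::group_by(results, .data$band),
    n = dplyr::n(),
    n_significant = sum(.data$significant, na.rm = TRUE),
    fraction_significant = .data$n_significant / .data$n,
    median_peak_freq = if (any(.data$significant, na.rm = TRUE)) {
      stats::median(.data$peak_freq[.data$significant], na.rm = TRUE)
    } else {
      NA_real_
    },
    .groups = "drop"
  )
}
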
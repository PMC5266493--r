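#' Per-epoch polysomnographic staging features
#'
#' For each fixed-length epoch, computes the features used to recognise
#' REM sleep: broadband EMG power (10-100 Hz), scalp delta power
#' (0.5-4 Hz), scalp spindle-band power (11-16 Hz), and the sum over
#' +/- 1 s lags of the demeaned cross-covariance of the two EOG channels.
#' Conjugate (opposite-polarity) rapid eye movements drive the EOG
#' cross-covariance sum negative.
#'
#' @param rec A [recording()] containing channels of modality `emg`,
#'   `scalp_eeg`, `eog_left` and `eog_right`.
#' @param epoch_length_s Epoch length in seconds.
#' @return Tibble with one row per complete epoch: `epoch_index`,
#'   `emg_power`, `delta_power`, `spindle_power`, `eog_xcov_sum`.
#' @export
epoch_features <- function(rec, epoch_length_s = 30) {
  emg <- modality_signal(rec, "emg")
  eeg <- modality_signal(rec, "scalp_eeg")
  eog_l <- modality_signal(rec, "eog_left")
  eog_r <- modality_signal(rec, "eog_right")
  fs <- rec$sample_rate
  spp <- round(epoch_length_s * fs)
  n_epochs <- floor(ncol(rec$signals) / spp)
  if (n_epochs < 1) stop("recording shorter than one epoch", call. = FALSE)
  emg_hi <- min(100, fs / 2 * 0.99)
  lag_max <- round(fs)
  res <- purrr::map_dfr(seq_len(n_epochs), function(k) {
    sel <- ((k - 1) * spp + 1):(k * spp)
    tibble::tibble(
      epoch_index = k,
      emg_power = fft_band_power(emg[sel], fs, 10, emg_hi),
      delta_power = fft_band_power(eeg[sel], fs, 0.5, 4),
      spindle_power = fft_band_power(eeg[sel], fs, 11, 16),
      eog_xcov_sum = lag_summed_crosscov(eog_l[sel], eog_r[sel], lag_max)
    )
  })
  res
}

# Sum over lags -L..L of the demeaned, 1/N-normalised cross-covariance of x
# and y (lag pairs truncated at the segment edges). Computed exactly via a
# running window sum: sum_t (x_t - xbar) * sum_{|u-t| <= L} (y_u - ybar).
lag_summed_crosscov <- function(x, y, lag_max) {
  n <- length(x)
  xd <- x - mean(x)
  yd <- y - mean(y)
  cs <- cumsum(c(0, yd))
  hi <- pmin(n, seq_len(n) + lag_max)
  lo <- pmax(1, seq_len(n) - lag_max)
  win_sum <- cs[hi + 1] - cs[lo]
  sum(xd * win_sum) / n
}

#' Threshold-based REM classification from staging features
#'
#' An epoch is labelled REM when all four criteria hold: EMG power at or
#' below the `q_emg` quantile of the night (REM atonia gives the lowest
#' EMG of the night), delta power at or below the `q_delta` quantile,
#' spindle power at or below the `q_spindle` quantile (low-voltage
#' irregular EEG without NREM graphoelements), and a negative EOG
#' cross-covariance sum (conjugate eye movements). Thresholds are
#' quantiles of the whole night because the defining EMG criterion is
#' intrinsically relative.
#'
#' @param features Output of [epoch_features()].
#' @param q_emg,q_delta,q_spindle Quantile thresholds in (0, 1).
#' @param epoch_length_s Epoch length used for the output hypnogram.
#' @return A [hypnogram()] with labels `REM` / `other`.
#' @export
classify_rem <- function(features, q_emg = 0.2, q_delta = 0.3,
                         q_spindle = 0.3, epoch_length_s = 30) {
  if (nrow(features) < 20) {
    stop("need at least 20 epochs to estimate quantile thresholds", call. = FALSE)
  }
  degenerate <- stats::sd(features$emg_power) == 0 &&
    stats::sd(features$delta_power) == 0 &&
    stats::sd(features$spindle_power) == 0
  if (degenerate) {
    warning("constant staging features; no REM labelled")
    return(hypnogram(rep("other", nrow(features)), epoch_length_s))
  }
  is_rem <-
    features$emg_power <= stats::quantile(features$emg_power, q_emg) &
    features$delta_power <= stats::quantile(features$delta_power, q_delta) &
    features$spindle_power <= stats::quantile(features$spindle_power, q_spindle) &
    features$eog_xcov_sum < 0
  hypnogram(ifelse(is_rem, "REM", "other"), epoch_length_s)
}
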
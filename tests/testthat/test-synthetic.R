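test_that("generators are pure functions of their seed", {
  x1 <- gen_background(10, 500, 1, -2, seed = 11)
  x2 <- gen_background(10, 500, 1, -2, seed = 11)
  expect_identical(x1, x2)
  b1 <- gen_burst_channel(20, 500, "beta", seed = 3)
  b2 <- gen_burst_channel(20, 500, "beta", seed = 3)
  expect_identical(b1$signal, b2$signal)
  expect_identical(b1$bursts, b2$bursts)
})

test_that("a zero exponent gives a flat-spectrum signal", {
  expect_warning(x <- gen_background(60, 500, 1, 0, seed = 5), "non-decaying")
  sp <- multitaper_spectrum(x[1:5000], 500)
  ft <- fit_power_law(sp)
  expect_lt(abs(ft$b), 0.1)
})

test_that("burst truth intervals have the length the band arithmetic dictates", {
  bc <- gen_burst_channel(60, 500, "beta", bursts_per_min = 4, n_cycles = 4,
                          seed = 2)
  # 4 cycles at the 25 Hz band centre = 160 ms
  expect_equal(unique(round(bc$bursts$end_s - bc$bursts$start_s, 6)), 0.16)
  # zero burst rate: pure background, empty truth
  none <- gen_burst_channel(20, 500, "beta", bursts_per_min = 0, seed = 2)
  expect_equal(nrow(none$bursts), 0)
})

test_that("coupled pairs approach unit coherence in the identical-signal limit", {
  # burst amplitude scales with the background, so the vanishing-background
  # limit is reached by sending the envelope SNR to infinity
  pr <- gen_coherent_pair(60, 500, "theta", mixing_weight = 1, lag_ms = 0,
                          snr = 1e6, seed = 4)
  w2 <- window_2s(tibble::tibble(start_s = 0, end_s = 60))
  wa <- remosc:::signal_windows(pr$a, 500, w2)
  wb <- remosc:::signal_windows(pr$b, 500, w2)
  coh <- pooled_coherence(wa, wb, 500, "theta")
  expect_gt(coh$coh_sq_center, 0.999)
})

test_that("session truth bursts stay inside REM blocks and the EMG shows atonia", {
  sess <- gen_session(small_scenario(seed = 6))
  hyp <- sess$truth$hypnogram
  len <- epoch_length_s(hyp)
  rem_runs <- remosc:::logical_runs(hyp$stage == "REM")
  in_rem <- function(t0, t1) {
    any(apply(rem_runs, 1, function(r) {
      t0 >= (r["start"] - 1) * len - 1e-9 & t1 <= r["end"] * len + 1e-9
    }))
  }
  bursts <- sess$truth$bursts
  expect_gt(nrow(bursts), 0)
  expect_true(all(mapply(in_rem, bursts$start_s, bursts$end_s)))
  # EMG variance drops at least 4-fold in REM vs wake
  emg <- remosc:::modality_signal(sess$recording, "emg")
  fs <- sess$recording$sample_rate
  stages <- sess$truth$scenario$stages
  ends <- cumsum(stages$duration_s)
  seg <- function(i) emg[(round((ends[i] - stages$duration_s[i]) * fs) + 1):round(ends[i] * fs)]
  v_w <- stats::var(seg(1))
  v_rem <- stats::var(seg(which(stages$stage == "REM")[1]))
  expect_gt(v_w / v_rem, 4)
})

test_that("EOG pair cross-covariance sums are negative during REM epochs", {
  sess <- gen_session(small_scenario(seed = 9))
  f <- epoch_features(sess$recording)
  rem <- sess$truth$hypnogram$stage == "REM"
  expect_lt(mean(f$eog_xcov_sum[rem]), 0)
  expect_gt(mean(f$eog_xcov_sum[rem] < 0), 0.9)
})

test_that("session generation is deterministic under a fixed seed", {
  s1 <- gen_session(small_scenario(seed = 3))
  s2 <- gen_session(small_scenario(seed = 3))
  expect_identical(s1$recording$signals, s2$recording$signals)
})

test_that("analyses are rate-agnostic at the 512 Hz native rate", {
  fs <- 512
  # slope recovery: window sample counts derive from the rate
  x <- gen_background(40, fs, 2, -2, seed = 55)
  sp <- multitaper_spectrum(x[1:(10 * fs)], fs)
  expect_equal(length(x), 40 * fs)
  ft <- fit_power_law(sp)
  expect_equal(ft$b, -2, tolerance = 0.3)
  # windowing arithmetic in seconds, independent of rate
  eps <- tibble::tibble(start_s = 0, end_s = 100)
  expect_equal(nrow(window_rem(eps)), 10)
  # burst detection at 512 Hz
  bc <- gen_burst_channel(120, fs, "beta", bursts_per_min = 2, n_cycles = 6,
                          snr = 12, seed = 56)
  ev <- detect_bursts(band_envelope(bc$signal, fs, "beta"), fs, "beta")
  expect_gte(nrow(ev), nrow(bc$bursts) - 1)
})
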
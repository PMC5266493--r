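# Synthetic recording generator. Every generator is a pure function of its
# seed (all randomness runs through withr::with_seed), and each returns the
# ground truth the downstream analyses are meant to recover.

#' Generate a 1/f-type background signal
#'
#' Shapes white noise in the frequency domain so that the expected
#' one-sided power spectrum equals `a_true * f^b_true` from 1 Hz up to the
#' Nyquist frequency (held flat below 1 Hz to keep the variance finite).
#' The declared calibration band for downstream fits is 2-50 Hz, safely
#' inside the shaped range.
#'
#' @param duration_s Duration in seconds (>= 10).
#' @param rate Sampling rate in Hz.
#' @param a_true Spectral scale (uV^2/Hz at 1 Hz).
#' @param b_true Spectral exponent (negative for a decaying spectrum; a
#'   non-negative value is allowed but warned as non-physiological).
#' @param seed Integer seed; identical seeds give identical signals.
#' @return Zero-mean numeric vector of length `duration_s * rate`.
#' @export
gen_background <- function(duration_s, rate, a_true = 1, b_true = -2, seed = 1) {
  stopifnot(duration_s >= 10, rate > 0)
  if (b_true >= 0) warning("b_true >= 0: non-decaying (non-physiological) spectrum")
  n <- round(duration_s * rate)
  nf <- floor(n / 2)
  f <- (1:nf) * rate / n
  S <- a_true * pmax(f, 1)^b_true
  withr::with_seed(seed, {
    amp <- sqrt(S * rate * n / 2)
    z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) / sqrt(2)
    X <- complex(real = numeric(n))
    X[2:(nf + 1)] <- amp * z
    if (n %% 2 == 0) X[nf + 1] <- sqrt(S[nf] * rate * n) * stats::rnorm(1)
    if (nf >= 2) X[n:(n - nf + 2)] <- Conj(X[2:nf])
    x <- Re(stats::fft(X, inverse = TRUE)) / n
    x - mean(x)
  })
}

# Expected variance of gen_background restricted to a band (analytic
# integral of the shaped spectrum).
band_variance_true <- function(band, a_true, b_true) {
  band <- as_band(band)
  lo <- max(band$f_lo, 1)
  hi <- band$f_hi
  if (abs(b_true + 1) < 1e-12) {
    a_true * log(hi / lo)
  } else {
    a_true * (hi^(b_true + 1) - lo^(b_true + 1)) / (b_true + 1)
  }
}

# Cosine-tapered (Tukey) amplitude window: raised-cosine onset and offset
# ramps each covering `taper_frac / 2` of the duration, with a flat top in
# between. The full support defines the ground-truth burst duration.
burst_window <- function(n, taper_frac = 0.5) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  r <- taper_frac / 2
  up <- t < r
  dn <- t > 1 - r
  w[up] <- 0.5 * (1 - cos(pi * t[up] / r))
  w[dn] <- 0.5 * (1 - cos(pi * (1 - t[dn]) / r))
  w
}

# Jittered-slot burst schedule: one burst per slot of 60/bursts_per_min
# seconds, uniformly placed within the slot, so bursts never overlap and
# the realised rate equals the requested rate.
schedule_bursts <- function(duration_s, bursts_per_min, burst_s) {
  if (bursts_per_min <= 0) return(numeric(0))
  slot <- 60 / bursts_per_min
  if (slot < burst_s) {
    stop("burst rate too high: bursts longer than their scheduling slot",
         call. = FALSE)
  }
  n_slots <- floor(duration_s / slot)
  if (n_slots < 1) return(numeric(0))
  (seq_len(n_slots) - 1) * slot + stats::runif(n_slots, 0, slot - burst_s)
}

# Additive burst train: sinusoids at the band centre under the tapered
# amplitude window. Returns the waveform and the truth intervals.
burst_train <- function(n, rate, band, bursts_per_min, n_cycles, amplitude) {
  band <- as_band(band)
  burst_s <- n_cycles / band$f_center
  starts <- schedule_bursts(n / rate, bursts_per_min, burst_s)
  x <- numeric(n)
  nb <- round(burst_s * rate)
  w <- burst_window(nb)
  for (s0 in starts) {
    i0 <- round(s0 * rate) + 1
    idx <- i0:(i0 + nb - 1)
    idx <- idx[idx <= n]
    tt <- (idx - i0) / rate
    x[idx] <- x[idx] + amplitude * w[seq_along(idx)] *
      sin(2 * pi * band$f_center * tt)
  }
  truth <- tibble::tibble(start_s = starts, end_s = starts + burst_s)
  list(signal = x, bursts = merge_intervals(truth))
}

# merge overlapping truth intervals (defensive; the slot schedule cannot
# overlap, but shifted copies can after concatenation)
merge_intervals <- function(iv) {
  if (nrow(iv) < 2) return(iv)
  iv <- iv[order(iv$start_s), ]
  out <- iv[1, ]
  for (i in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv$start_s[i] <= out$end_s[last]) {
      out$end_s[last] <- max(out$end_s[last], iv$end_s[i])
    } else {
      out <- dplyr::bind_rows(out, iv[i, ])
    }
  }
  out
}

# burst amplitude for a target envelope SNR: peak envelope power A^2 equals
# snr times the mean envelope power (2 * band variance) of the background.
burst_amplitude <- function(snr, a_true, b_true, band) {
  sqrt(2 * snr * band_variance_true(band, a_true, b_true))
}

#' Generate a channel with band-limited oscillatory bursts
#'
#' A 1/f background plus additive bursts: each burst is a sinusoid at the
#' band centre frequency under a cosine-tapered amplitude window lasting
#' `n_cycles / f_center` seconds. The peak amplitude is set so that the
#' burst's peak envelope power is `snr` times the background's mean
#' band-envelope power. Burst onsets are scheduled in jittered
#' non-overlapping slots at the requested rate.
#'
#' @inheritParams gen_background
#' @param band Target band (see [as_band()]).
#' @param bursts_per_min Burst rate (0 gives pure background and an empty
#'   truth list).
#' @param n_cycles Burst duration in cycles of the band centre (>= 2).
#' @param snr Peak envelope power of a burst relative to the background's
#'   mean band-envelope power (> 0).
#' @return List with `signal`, `bursts` (tibble of true `start_s`,
#'   `end_s`), `band`, `amplitude`.
#' @export
gen_burst_channel <- function(duration_s, rate, band, bursts_per_min = 6,
                              n_cycles = 6, snr = 10, a_true = 1,
                              b_true = -2, seed = 1) {
  stopifnot(n_cycles >= 2, snr > 0)
  band <- as_band(band)
  bg <- gen_background(duration_s, rate, a_true, b_true, seed)
  amp <- burst_amplitude(snr, a_true, b_true, band)
  tr <- withr::with_seed(seed + 1L, {
    burst_train(length(bg), rate, band, bursts_per_min, n_cycles, amp)
  })
  list(
    signal = bg + tr$signal,
    bursts = tr$bursts,
    band = band,
    amplitude = amp
  )
}

#' Generate a pair of channels with known coupling and envelope lag
#'
#' Channel A carries a shared burst source plus a private background;
#' channel B carries the shared source delayed by `lag_ms` and scaled by
#' `mixing_weight`, plus an independent private burst source scaled by
#' `1 - mixing_weight`, plus its own background. Positive `lag_ms` means A
#' precedes B. With `mixing_weight = 0` the channels are independent; with
#' `mixing_weight = 1` and vanishing background they coincide up to the
#' delay.
#'
#' @inheritParams gen_burst_channel
#' @param mixing_weight Shared-source weight in `[0, 1]`.
#' @param lag_ms Envelope delay of B relative to A in ms (|lag| < 500).
#' @return List with `a`, `b` (signals), `bursts_a`, `bursts_b` (truth
#'   intervals), `mixing_weight`, `lag_ms`, `band`.
#' @export
gen_coherent_pair <- function(duration_s, rate, band, bursts_per_min = 6,
                              n_cycles = 6, snr = 10, mixing_weight = 0.8,
                              lag_ms = 0, a_true = 1, b_true = -2, seed = 1) {
  stopifnot(mixing_weight >= 0, mixing_weight <= 1, abs(lag_ms) < 500)
  band <- as_band(band)
  burst_s <- n_cycles / band$f_center
  if (abs(lag_ms) / 1000 > burst_s) {
    warning("lag exceeds the burst length; envelope overlap may vanish")
  }
  n <- round(duration_s * rate)
  amp <- burst_amplitude(snr, a_true, b_true, band)
  shared <- withr::with_seed(seed + 1L, {
    burst_train(n, rate, band, bursts_per_min, n_cycles, amp)
  })
  private <- withr::with_seed(seed + 2L, {
    burst_train(n, rate, band, bursts_per_min, n_cycles, amp)
  })
  lag_n <- round(lag_ms / 1000 * rate)
  shift_sig <- function(x, k) {
    if (k == 0) return(x)
    if (k > 0) c(numeric(k), x[1:(length(x) - k)])
    else c(x[(-k + 1):length(x)], numeric(-k))
  }
  bg_a <- gen_background(duration_s, rate, a_true, b_true, seed + 3L)
  bg_b <- gen_background(duration_s, rate, a_true, b_true, seed + 4L)
  sig_a <- shared$signal + bg_a
  sig_b <- mixing_weight * shift_sig(shared$signal, lag_n) +
    (1 - mixing_weight) * private$signal + bg_b
  bursts_b <- dplyr::mutate(
    shared$bursts,
    start_s = .data$start_s + lag_n / rate,
    end_s = .data$end_s + lag_n / rate
  )
  list(
    a = sig_a, b = sig_b,
    bursts_a = shared$bursts,
    bursts_b = merge_intervals(dplyr::bind_rows(bursts_b, private$bursts)),
    mixing_weight = mixing_weight, lag_ms = lag_ms, band = band
  )
}

# band-limited Gaussian noise with a flat spectrum inside [f_lo, f_hi] and
# the requested standard deviation (used for delta and spindle content of
# the scalp channel)
gen_band_noise <- function(n, rate, f_lo, f_hi, sd_target) {
  nf <- floor(n / 2)
  f <- (1:nf) * rate / n
  mask <- f >= f_lo & f <= f_hi
  X <- complex(real = numeric(n))
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf))
  X[2:(nf + 1)] <- ifelse(mask, 1, 0) * z
  if (nf >= 2) X[n:(n - nf + 2)] <- Conj(X[2:nf])
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x * sd_target / s
  x
}

# monophasic saccade-like deflection (smooth bump): a rapid eye movement
# shifts the corneoretinal potential, deflecting the two EOG leads in
# opposite directions; the non-zero integral makes the lag-summed
# cross-covariance of the pair strongly negative
saccade_pulse <- function(rate, dur_s = 0.35) {
  n <- round(dur_s * rate)
  t <- seq(0, 1, length.out = n)
  sin(pi * t)^2
}

#' Scenario specification for a synthetic sleep session
#'
#' Bundles the hypnogram plan and all generator parameters consumed by
#' [gen_session()]. Defaults describe a compact 60 min night with a single
#' 10.5 min REM block (17.5% REM), one theta-coupled DLPFC-ACC depth pair,
#' NREM delta and spindle content on the scalp channel, four-fold-plus EMG
#' atonia during REM, and conjugate opposite-polarity EOG deflections
#' during REM.
#'
#' @param stages Tibble with columns `stage` (W/N1/N2/N3/REM) and
#'   `duration_s`, in session order.
#' @param rate Sampling rate in Hz.
#' @param a_true,b_true Background spectral scale and exponent shared by
#'   all channels.
#' @param depth_channels Tibble describing depth channels: `label`,
#'   `region`, `band`, `bursts_per_min`, `n_cycles`, `snr`. Burst content
#'   is added during REM blocks only.
#' @param pairs Tibble describing coupled channel pairs: `chan_a`,
#'   `chan_b`, `band`, `mixing_weight`, `lag_ms`. Paired channels share a
#'   delayed burst source during REM blocks.
#' @param emg_sd Named numeric vector of EMG noise SD (uV) per stage.
#' @param eog_amp Saccade pulse amplitude in uV.
#' @param seed Integer seed.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(
    stages = tibble::tibble(
      stage = c("W", "N1", "N2", "N3", "N2", "REM", "N2", "W"),
      duration_s = c(300, 150, 900, 750, 420, 630, 300, 150)
    ),
    rate = 500,
    a_true = 30,
    b_true = -2,
    depth_channels = tibble::tibble(
      label = c("dDLPFC1", "dACC1"),
      region = c("DLPFC", "ACC"),
      band = c("beta", "beta"),
      bursts_per_min = c(6, 6),
      n_cycles = c(5, 5),
      snr = c(10, 10)
    ),
    pairs = tibble::tibble(
      chan_a = "dDLPFC1", chan_b = "dACC1",
      band = "theta", mixing_weight = 0.8, lag_ms = 22,
      bursts_per_min = 6, n_cycles = 6, snr = 10
    ),
    emg_sd = c(W = 30, N1 = 18, N2 = 15, N3 = 15, REM = 7),
    eog_amp = 80,
    seed = 1) {
  stopifnot(all(stages$duration_s > 0))
  if (nrow(pairs)) {
    stopifnot(all(pairs$mixing_weight >= 0 & pairs$mixing_weight <= 1))
  }
  structure(
    list(
      stages = stages, rate = rate, a_true = a_true, b_true = b_true,
      depth_channels = depth_channels, pairs = pairs,
      emg_sd = emg_sd, eog_amp = eog_amp, seed = seed
    ),
    class = "scenario_spec"
  )
}

#' Generate a full synthetic sleep session
#'
#' Builds a multichannel [recording()] (depth channels, scalp EEG, EMG,
#' EOG pair), its true [hypnogram()], and a ground-truth bundle (burst
#' intervals, pair couplings, background parameters). Depth burst and
#' coupling content appears during REM blocks only; the scalp channel
#' carries strong delta in N3, moderate delta plus spindle-band bursts in
#' N2; EMG variance drops at least four-fold in REM relative to wake; the
#' EOG pair shows opposite-polarity deflection trains during REM (and
#' sparser ones during wake).
#'
#' @param spec A [scenario_spec()].
#' @return List with elements `recording`, `hypnogram`, `truth` (list:
#'   `hypnogram`, `bursts`, `pairs`, `a_true`, `b_true`, `scenario`).
#' @export
gen_session <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  rate <- spec$rate
  total_s <- sum(spec$stages$duration_s)
  n <- round(total_s * rate)
  blocks <- dplyr::mutate(
    spec$stages,
    end_s = cumsum(.data$duration_s),
    start_s = .data$end_s - .data$duration_s
  )
  rem_blocks <- blocks[blocks$stage == "REM", , drop = FALSE]
  child <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      (spec$seed * 1009L + counter) %% 2147483647L
    }
  })

  paired <- unique(c(spec$pairs$chan_a, spec$pairs$chan_b))
  truth_bursts <- list()
  sig <- list()

  # depth channels: background plus per-REM-block burst content
  for (i in seq_len(nrow(spec$depth_channels))) {
    cfg <- spec$depth_channels[i, ]
    x <- gen_background(total_s, rate, spec$a_true, spec$b_true, child())
    band <- as_band(cfg$band)
    amp <- burst_amplitude(cfg$snr, spec$a_true, spec$b_true, band)
    for (j in seq_len(nrow(rem_blocks))) {
      nb <- round(rem_blocks$duration_s[j] * rate)
      tr <- withr::with_seed(child(), {
        burst_train(nb, rate, band, cfg$bursts_per_min, cfg$n_cycles, amp)
      })
      i0 <- round(rem_blocks$start_s[j] * rate)
      x[(i0 + 1):(i0 + nb)] <- x[(i0 + 1):(i0 + nb)] + tr$signal
      if (nrow(tr$bursts)) {
        truth_bursts[[length(truth_bursts) + 1]] <- dplyr::mutate(
          tr$bursts,
          channel = cfg$label, band = band$name,
          start_s = .data$start_s + rem_blocks$start_s[j],
          end_s = .data$end_s + rem_blocks$start_s[j]
        )
      }
    }
    sig[[cfg$label]] <- x
  }

  # coupled pairs: shared delayed source added to both members in REM blocks
  for (i in seq_len(nrow(spec$pairs))) {
    pr <- spec$pairs[i, ]
    band <- as_band(pr$band)
    amp <- burst_amplitude(pr$snr, spec$a_true, spec$b_true, band)
    lag_n <- round(pr$lag_ms / 1000 * rate)
    for (j in seq_len(nrow(rem_blocks))) {
      nb <- round(rem_blocks$duration_s[j] * rate)
      tr <- withr::with_seed(child(), {
        burst_train(nb, rate, band, pr$bursts_per_min, pr$n_cycles, amp)
      })
      priv <- withr::with_seed(child(), {
        burst_train(nb, rate, band, pr$bursts_per_min, pr$n_cycles, amp)
      })
      shifted <- if (lag_n == 0) tr$signal else if (lag_n > 0) {
        c(numeric(lag_n), tr$signal[1:(nb - lag_n)])
      } else {
        c(tr$signal[(-lag_n + 1):nb], numeric(-lag_n))
      }
      i0 <- round(rem_blocks$start_s[j] * rate)
      idx <- (i0 + 1):(i0 + nb)
      sig[[pr$chan_a]][idx] <- sig[[pr$chan_a]][idx] + tr$signal
      sig[[pr$chan_b]][idx] <- sig[[pr$chan_b]][idx] +
        pr$mixing_weight * shifted + (1 - pr$mixing_weight) * priv$signal
      if (nrow(tr$bursts)) {
        truth_bursts[[length(truth_bursts) + 1]] <- dplyr::mutate(
          tr$bursts,
          channel = pr$chan_a, band = band$name,
          start_s = .data$start_s + rem_blocks$start_s[j],
          end_s = .data$end_s + rem_blocks$start_s[j]
        )
      }
    }
  }

  # scalp EEG: REM is low-voltage irregular (attenuated background), wake
  # carries alpha, N2 delta plus spindle-band bursts, N3 strong delta
  scalp <- gen_background(total_s, rate, spec$a_true / 2, spec$b_true, child())
  spindle_band <- canonical_bands()$spindle
  withr::with_seed(child(), {
    for (j in seq_len(nrow(blocks))) {
      stg <- blocks$stage[j]
      nb <- round(blocks$duration_s[j] * rate)
      i0 <- round(blocks$start_s[j] * rate)
      idx <- (i0 + 1):(i0 + nb)
      if (stg == "REM") {
        scalp[idx] <- scalp[idx] * 0.5
      } else if (stg == "W") {
        scalp[idx] <- scalp[idx] + gen_band_noise(nb, rate, 8, 12, 12)
      } else if (stg %in% c("N2", "N3")) {
        delta_sd <- if (stg == "N3") 40 else 15
        scalp[idx] <- scalp[idx] + gen_band_noise(nb, rate, 0.5, 4, delta_sd)
        if (stg == "N2") {
          tr <- burst_train(nb, rate, spindle_band, 12, 10, 25)
          scalp[idx] <- scalp[idx] + tr$signal
        }
      }
    }
  })

  # EMG: stage-dependent white noise (atonia in REM)
  emg <- withr::with_seed(child(), {
    out <- numeric(n)
    for (j in seq_len(nrow(blocks))) {
      nb <- round(blocks$duration_s[j] * rate)
      i0 <- round(blocks$start_s[j] * rate)
      out[(i0 + 1):(i0 + nb)] <- stats::rnorm(nb, sd = spec$emg_sd[[blocks$stage[j]]])
    }
    out
  })

  # EOG: small background each eye plus conjugate opposite-polarity
  # saccade trains in REM (sparser in wake)
  eog_l <- gen_background(total_s, rate, spec$a_true / 6, spec$b_true, child())
  eog_r <- gen_background(total_s, rate, spec$a_true / 6, spec$b_true, child())
  pulse <- saccade_pulse(rate)
  withr::with_seed(child(), {
    for (j in seq_len(nrow(blocks))) {
      stg <- blocks$stage[j]
      if (!stg %in% c("REM", "W")) next
      rate_per_s <- if (stg == "REM") 0.6 else 0.15
      n_ev <- stats::rpois(1, rate_per_s * blocks$duration_s[j])
      if (n_ev < 1) next
      starts <- sort(stats::runif(n_ev, 0, blocks$duration_s[j] - 0.5))
      for (s0 in starts) {
        i0 <- round((blocks$start_s[j] + s0) * rate)
        idx <- (i0 + 1):(i0 + length(pulse))
        idx <- idx[idx <= n]
        amp <- spec$eog_amp * stats::runif(1, 0.6, 1)
        eog_l[idx] <- eog_l[idx] + amp * pulse[seq_along(idx)]
        eog_r[idx] <- eog_r[idx] - amp * pulse[seq_along(idx)]
      }
    }
  })

  labels <- c(names(sig), "scalpC3", "EMG1", "EOGL", "EOGR")
  signals <- rbind(
    do.call(rbind, sig),
    scalpC3 = scalp, EMG1 = emg, EOGL = eog_l, EOGR = eog_r
  )
  channels <- dplyr::bind_rows(
    tibble::tibble(
      label = names(sig), modality = "depth",
      region = spec$depth_channels$region[match(names(sig), spec$depth_channels$label)],
      shaft_id = paste0("S", seq_along(sig)),
      contact_index = 1L, gray_matter = TRUE, excluded = FALSE
    ),
    tibble::tibble(
      label = c("scalpC3", "EMG1", "EOGL", "EOGR"),
      modality = c("scalp_eeg", "emg", "eog_left", "eog_right"),
      region = "other", shaft_id = NA_character_,
      contact_index = NA_integer_, gray_matter = FALSE, excluded = FALSE
    )
  )
  hyp <- hypnogram(
    rep(blocks$stage, times = round(blocks$duration_s / 30)),
    epoch_length_s = 30
  )
  bursts <- if (length(truth_bursts)) {
    dplyr::arrange(dplyr::bind_rows(truth_bursts), .data$channel, .data$start_s)
  } else {
    tibble::tibble(start_s = numeric(), end_s = numeric(),
                   channel = character(), band = character())
  }
  list(
    recording = recording(signals, rate, channels),
    hypnogram = hyp,
    truth = list(
      hypnogram = hyp, bursts = bursts, pairs = spec$pairs,
      a_true = spec$a_true, b_true = spec$b_true, scenario = spec
    )
  )
}

#' Export a synthetic session to disk
#'
#' Writes the recording as EDF, the channel metadata as a montage CSV,
#' the true hypnogram as CSV, and the ground truth (burst intervals, pair
#' couplings, background parameters) as JSON.
#'
#' @param session Output of [gen_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; files `recording.edf`, `montage.csv`,
#'   `hypnogram.csv`, `truth.json`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edf(session$recording, file.path(dir, "recording.edf"))
  write_montage_csv(session$recording$channels, file.path(dir, "montage.csv"))
  write_hypnogram_csv(session$hypnogram, file.path(dir, "hypnogram.csv"))
  truth <- list(
    a_true = session$truth$a_true,
    b_true = session$truth$b_true,
    bursts = session$truth$bursts,
    pairs = session$truth$pairs,
    stages = session$truth$scenario$stages
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
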
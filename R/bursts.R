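#' Instantaneous band-amplitude envelope
#'
#' Zero-phase FIR band-pass filtering (Hamming-window design; transition
#' width 1 Hz for bands starting below 10 Hz, 2 Hz otherwise) followed by
#' the magnitude of the analytic signal (Hilbert transform). The output
#' has the same length as the input; samples within one filter length of
#' either edge are flagged in the `edge` attribute.
#'
#' @param x Signal vector (uV).
#' @param rate Sampling rate (Hz).
#' @param band Band (see [as_band()]).
#' @param transition_hz Optional filter transition width override (Hz).
#' @return Numeric envelope vector with attribute `edge` (logical vector
#'   marking edge-contaminated samples).
#' @export
band_envelope <- function(x, rate, band, transition_hz = NULL) {
  band <- as_band(band)
  filt <- design_bandpass(band, rate, transition_hz)
  if (length(x) < 2 * filt$length) {
    stop("signal too short for the band-pass filter (need at least ",
         2 * filt$length, " samples)", call. = FALSE)
  }
  env <- hilbert_envelope(filter_zerophase(x, filt$h))
  edge <- rep(FALSE, length(x))
  ne <- min(filt$length, length(x))
  edge[1:ne] <- TRUE
  edge[(length(x) - ne + 1):length(x)] <- TRUE
  attr(env, "edge") <- edge
  env
}

#' Detect oscillatory bursts from a band-power envelope
#'
#' Power is the squared envelope. The threshold is
#' `median(power) + threshold_sd * sd(power)`, both statistics computed
#' over the supplied envelope (one REM episode). Maximal runs strictly
#' above threshold are kept if they last at least
#' `min_cycles / f_center` seconds; runs separated by less than one cycle
#' are merged before the duration test (sub-cycle envelope dips should not
#' split a burst).
#'
#' @param envelope Envelope from [band_envelope()] covering the episode.
#' @param rate Sampling rate (Hz).
#' @param band Band (see [as_band()]).
#' @param threshold_sd Threshold in SD units above the median (default 3).
#' @param min_cycles Minimum burst duration in centre-frequency cycles.
#' @param merge_gap_cycles Gap (cycles) below which adjacent runs merge;
#'   set to 0 to disable merging.
#' @param electrode_id Identifier carried into the result.
#' @return Tibble of burst events: `electrode_id`, `band`, `start_s`,
#'   `end_s`, `peak_power`, sorted and disjoint. A constant envelope gives
#'   zero bursts (the SD is 0 and no sample strictly exceeds the median).
#' @export
detect_bursts <- function(envelope, rate, band, threshold_sd = 3,
                          min_cycles = 2, merge_gap_cycles = 1,
                          electrode_id = NA_character_) {
  band <- as_band(band)
  p <- as.numeric(envelope)^2
  thr <- stats::median(p) + threshold_sd * stats::sd(p)
  runs <- logical_runs(p > thr)
  empty <- tibble::tibble(
    electrode_id = character(), band = character(),
    start_s = numeric(), end_s = numeric(), peak_power = numeric()
  )
  if (!nrow(runs)) return(empty)
  cycle_n <- rate / band$f_center
  # merge runs separated by less than one cycle
  if (merge_gap_cycles > 0 && nrow(runs) > 1) {
    merged <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[i, "start"] - last["end"] - 1 < merge_gap_cycles * cycle_n) {
        last["end"] <- runs[i, "end"]
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, merged)
  }
  dur_ok <- (runs[, "end"] - runs[, "start"] + 1) >= min_cycles * cycle_n
  runs <- runs[dur_ok, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  tibble::tibble(
    electrode_id = electrode_id,
    band = band$name,
    start_s = (runs[, "start"] - 1) / rate,
    end_s = runs[, "end"] / rate,
    peak_power = vapply(seq_len(nrow(runs)), function(i) {
      max(p[runs[i, "start"]:runs[i, "end"]])
    }, numeric(1))
  )
}

#' Burst occupancy raster across derivations
#'
#' Boolean derivation-by-time-bin matrix: a bin is `TRUE` when it overlaps
#' any burst of that derivation.
#'
#' @param bursts Tibble of burst events (from [detect_bursts()], possibly
#'   several electrodes bound together) with `electrode_id`, `start_s`,
#'   `end_s`.
#' @param electrode_ids Row order of the raster (defaults to the
#'   electrodes present).
#' @param start_s,end_s Time span of the raster in seconds.
#' @param bin_s Bin width in seconds.
#' @return Logical matrix (derivations x bins) with electrode row names;
#'   bin start times in the `bin_start_s` attribute.
#' @export
burst_raster <- function(bursts, electrode_ids = unique(bursts$electrode_id),
                         start_s, end_s, bin_s = 1) {
  edges <- seq(start_s, end_s, by = bin_s)
  n_bins <- length(edges) - 1
  m <- matrix(FALSE, nrow = length(electrode_ids), ncol = n_bins,
              dimnames = list(electrode_ids, NULL))
  for (i in seq_len(nrow(bursts))) {
    r <- match(bursts$electrode_id[i], electrode_ids)
    if (is.na(r)) next
    hit <- which(edges[-length(edges)] < bursts$end_s[i] &
                   edges[-1] > bursts$start_s[i])
    m[r, hit] <- TRUE
  }
  attr(m, "bin_start_s") <- edges[-length(edges)]
  m
}
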
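#' Divide REM episodes into 2 s coherence windows
#'
#' Non-overlapping 2 s windows pooled across all REM episodes of the
#' session; a single coherence estimate is later formed from all of them.
#'
#' @param episodes Tibble of episodes with `start_s`, `end_s`.
#' @param window_s Window length in seconds (default 2).
#' @return Tibble with `episode`, `window`, `start_s`, `end_s`.
#' @export
window_2s <- function(episodes, window_s = 2) {
  window_rem(episodes, window_s = window_s)
}

#' Multitaper parameters for a band-integrating coherence estimate
#'
#' The half-bandwidth is set to half the band width, so the estimate read
#' at the band centre integrates the entire band of interest. The
#' time-bandwidth product is then `window_s * W` and the taper count the
#' usual `floor(2 * window_s * W) - 1`.
#'
#' @param band Band (see [as_band()]).
#' @param window_s Analysis window length (s).
#' @return List with `time_halfbandwidth` (= `window_s * W`, dimensionless)
#'   and `n_tapers`.
#' @export
band_taper_params <- function(band, window_s = 2) {
  band <- as_band(band)
  W <- (band$f_hi - band$f_lo) / 2
  tw <- window_s * W
  k <- floor(2 * tw) - 1
  if (k < 1) {
    stop("band too narrow for a ", window_s,
         " s window (would need ", k, " tapers)", call. = FALSE)
  }
  list(time_halfbandwidth = tw, n_tapers = k)
}

#' Pooled multitaper coherence between two channels
#'
#' Magnitude-squared coherence pooled over all windows and tapers:
#' `|C(f)|^2 = |sum S_ab|^2 / (sum S_aa * sum S_bb)`, with the sums
#' running over every window-taper combination. The band value is read at
#' the grid frequency nearest the band centre, where the taper bandwidth
#' spans the whole band. The degrees of freedom `m` equal the number of
#' windows times the number of tapers.
#'
#' @param windows_a,windows_b Samples-by-windows matrices (equal sizes,
#'   aligned in time), e.g. from [signal_windows()].
#' @param rate Sampling rate (Hz).
#' @param band Band (see [as_band()]).
#' @param n_tapers Optional cap on the taper count (default: the value
#'   from [band_taper_params()]).
#' @return Object of class `coherence_estimate`: list with `freq`,
#'   `coh_sq` (full spectrum), `coh_sq_center`, `center_freq`, `m`,
#'   `n_windows`, `n_tapers`, `band`, and the per-window-taper
#'   centre-frequency cross-spectral coefficients (`xc`, `yc`) reused by
#'   the permutation test.
#' @export
pooled_coherence <- function(windows_a, windows_b, rate, band,
                             n_tapers = NULL) {
  stopifnot(is.matrix(windows_a), is.matrix(windows_b),
            all(dim(windows_a) == dim(windows_b)))
  band <- as_band(band)
  n <- nrow(windows_a)
  nwin <- ncol(windows_a)
  window_s <- n / rate
  par <- band_taper_params(band, window_s)
  k <- if (is.null(n_tapers)) par$n_tapers else min(n_tapers, par$n_tapers)
  V <- dpss_tapers(n, par$time_halfbandwidth, k)
  nf <- floor(n / 2) + 1
  freq <- (0:(nf - 1)) * rate / n
  saa <- numeric(nf); sbb <- numeric(nf)
  sab <- complex(real = numeric(nf))
  ic <- which.min(abs(freq - band$f_center))
  xc <- matrix(complex(real = 0), nwin, k)
  yc <- matrix(complex(real = 0), nwin, k)
  for (w in seq_len(nwin)) {
    xa <- windows_a[, w] - mean(windows_a[, w])
    xb <- windows_b[, w] - mean(windows_b[, w])
    A <- stats::mvfft(V * xa)[1:nf, , drop = FALSE]
    B <- stats::mvfft(V * xb)[1:nf, , drop = FALSE]
    saa <- saa + rowSums(Mod(A)^2)
    sbb <- sbb + rowSums(Mod(B)^2)
    sab <- sab + rowSums(A * Conj(B))
    xc[w, ] <- A[ic, ]
    yc[w, ] <- B[ic, ]
  }
  if (saa[ic] == 0 || sbb[ic] == 0) {
    stop("zero auto-spectrum at the band centre", call. = FALSE)
  }
  coh_sq <- Mod(sab)^2 / (saa * sbb)
  structure(
    list(
      freq = freq, coh_sq = coh_sq,
      coh_sq_center = coh_sq[ic], center_freq = freq[ic],
      m = nwin * k, n_windows = nwin, n_tapers = k,
      band = band, xc = xc, yc = yc
    ),
    class = "coherence_estimate"
  )
}

#' @export
print.coherence_estimate <- function(x, ...) {
  cat(sprintf(
    "<coherence_estimate> |C|^2 = %.4f at %.2f Hz (%s band, m = %d)\n",
    x$coh_sq_center, x$center_freq, x$band$name, x$m
  ))
  invisible(x)
}

#' Analytic p-value for pooled coherence under zero true coherence
#'
#' Under the null of zero coherence the pooled magnitude-squared
#' coherence with `m` degrees of freedom follows a Beta(1, m-1) law with
#' density `(m-1) * (1-x)^(m-2)`; the upper-tail probability is
#' `(1 - coh_sq)^(m-1)`.
#'
#' @param coh_sq Magnitude-squared coherence in `[0, 1]` (vectorised).
#' @param m Degrees of freedom (windows x tapers, >= 2).
#' @return Upper-tail probability.
#' @export
analytic_pvalue <- function(coh_sq, m) {
  if (any(m < 2)) stop("m must be at least 2", call. = FALSE)
  stopifnot(all(coh_sq >= 0 & coh_sq <= 1))
  (1 - coh_sq)^(m - 1)
}

#' Significance threshold for pooled coherence
#' @param alpha Significance level.
#' @param m Degrees of freedom.
#' @return The magnitude-squared coherence exceeded with probability
#'   `alpha` under the null: `1 - alpha^(1/(m-1))`.
#' @export
coherence_threshold <- function(alpha, m) 1 - alpha^(1 / (m - 1))

#' Permutation p-value for pooled coherence
#'
#' Re-computes the pooled band-centre coherence after permuting the order
#' of one channel's windows (tapers stay aligned; marginal spectra are
#' preserved, only the window pairing is destroyed). The p-value uses the
#' add-one rule `(1 + #{shuffle >= observed}) / (1 + n_shuffles)`.
#'
#' @param coh A `coherence_estimate` from [pooled_coherence()].
#' @param n_shuffles Number of permutations (default 2000; fewer than 100
#'   is warned as poorly resolved).
#' @param seed Integer seed for the permutation stream.
#' @return Permutation p-value.
#' @export
mc_pvalue <- function(coh, n_shuffles = 2000, seed = 1) {
  stopifnot(inherits(coh, "coherence_estimate"))
  if (coh$n_windows < 20) {
    stop("need at least 20 windows for the permutation test", call. = FALSE)
  }
  if (n_shuffles < 100) warning("fewer than 100 shuffles: poor p-value resolution")
  xc <- coh$xc; yc <- coh$yc
  denom <- sum(Mod(xc)^2) * sum(Mod(yc)^2)
  obs <- Mod(sum(xc * Conj(yc)))^2 / denom
  nwin <- nrow(xc)
  withr::with_seed(seed, {
    ge <- 0L
    for (s in seq_len(n_shuffles)) {
      perm <- sample.int(nwin)
      stat <- Mod(sum(xc * Conj(yc[perm, , drop = FALSE])))^2 / denom
      if (stat >= obs - 1e-15) ge <- ge + 1L
    }
    (1 + ge) / (1 + n_shuffles)
  })
}

#' Coherence test for one channel pair
#'
#' Convenience wrapper: pooled coherence over the supplied windows plus
#' the analytic and permutation p-values.
#'
#' @param xa,xb Signal vectors.
#' @param rate Sampling rate (Hz).
#' @param windows Window table from [window_2s()].
#' @param band Band (see [as_band()]).
#' @param n_shuffles,seed Permutation settings (see [mc_pvalue()]).
#' @param pair_id Identifier carried into the result.
#' @return One-row tibble: `pair_id`, `band`, `coh_sq_center`, `m`,
#'   `n_windows`, `n_tapers`, `p_analytic`, `p_mc`.
#' @export
coherence_test <- function(xa, xb, rate, windows, band, n_shuffles = 2000,
                           seed = 1, pair_id = NA_character_) {
  wa <- signal_windows(xa, rate, windows)
  wb <- signal_windows(xb, rate, windows)
  coh <- pooled_coherence(wa, wb, rate, band)
  tibble::tibble(
    pair_id = pair_id,
    band = coh$band$name,
    coh_sq_center = coh$coh_sq_center,
    m = coh$m,
    n_windows = coh$n_windows,
    n_tapers = coh$n_tapers,
    p_analytic = analytic_pvalue(coh$coh_sq_center, coh$m),
    p_mc = mc_pvalue(coh, n_shuffles, seed)
  )
}

#' Bonferroni-corrected significance over a set of pairs
#'
#' A pair is significant when both the analytic and the permutation
#' p-value fall below `alpha / n_pairs` (both methods must agree).
#'
#' @param results Tibble of [coherence_test()] rows.
#' @param alpha Family-wise significance level.
#' @return `results` with a `significant` column added; the per-band
#'   summary (fraction of significant pairs) is attached as the
#'   `"summary"` attribute and also available via [summarize_pairs()].
#' @export
pair_significance <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) >= 1)
  out <- dplyr::mutate(
    dplyr::group_by(results, .data$band),
    significant = .data$p_analytic < alpha / dplyr::n() &
      .data$p_mc < alpha / dplyr::n()
  )
  out <- dplyr::ungroup(out)
  attr(out, "summary") <- summarize_pairs(out)
  out
}

#' @rdname pair_significance
#' @export
summarize_pairs <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$band),
    n_pairs = dplyr::n(),
    n_significant = sum(.data$significant),
    fraction_significant = .data$n_significant / .data$n_pairs,
    .groups = "drop"
  )
}
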
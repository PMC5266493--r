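# Discrete prolate spheroidal (Slepian) tapers and multitaper spectra.
#
# The tapers are computed from the classical symmetric tridiagonal
# formulation of the concentration problem: the k most concentrated
# sequences are the eigenvectors belonging to the k largest eigenvalues of
# the tridiagonal matrix with diagonal ((N-1-2t)/2)^2 cos(2*pi*W) and
# off-diagonal t(N-t)/2. Eigenvalues are located by Sturm-sequence
# bisection (vectorised over the k targets) and eigenvectors recovered by
# inverse iteration with a tridiagonal (Thomas) solve, then orthonormalised.
# Results are cached per (n, nw, k).

.dpss_cache <- new.env(parent = emptyenv())

#' Slepian (DPSS) tapers
#'
#' @param n Taper length in samples.
#' @param nw Time-halfbandwidth product (dimensionless).
#' @param k Number of tapers; must satisfy `k <= 2 * nw - 1` to keep
#'   sidelobe leakage controlled.
#' @return An `n` x `k` matrix with orthonormal columns, ordered by
#'   decreasing spectral concentration. Sign convention: even-order tapers
#'   have positive mean, odd-order tapers positive initial slope.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 4, nw > 0, k >= 1)
  if (k > 2 * nw - 1) {
    stop("n_tapers must not exceed 2 * time_halfbandwidth - 1 ",
         "(requested ", k, " with nw = ", nw, ")", call. = FALSE)
  }
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  W <- nw / n
  ct <- cos(2 * pi * W)
  t0 <- 0:(n - 1)
  d <- ((n - 1 - 2 * t0) / 2)^2 * ct
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  e2 <- e^2

  # eigenvalue count below each shift (Sturm sequence), vectorised over shifts
  sturm_count <- function(x) {
    cnt <- integer(length(x))
    q <- d[1] - x
    cnt <- cnt + (q < 0)
    for (i in 2:n) {
      q <- ifelse(abs(q) < 1e-300, -1e-300, q)
      q <- d[i] - x - e2[i - 1] / q
      cnt <- cnt + (q < 0)
    }
    cnt
  }

  lo0 <- min(d - c(0, e) - c(e, 0))
  hi0 <- max(d + c(0, e) + c(e, 0))
  lo <- rep(lo0, k); hi <- rep(hi0, k)
  rank_wanted <- n - k + seq_len(k) # ascending ranks of the k largest
  scale <- max(abs(lo0), abs(hi0))
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    cnt <- sturm_count(mid)
    go_down <- cnt >= rank_wanted # at least `rank` eigenvalues below mid
    hi <- ifelse(go_down, mid, hi)
    lo <- ifelse(go_down, lo, mid)
    if (max(hi - lo) < 1e-10 * scale) break
  }
  lam <- (lo + hi) / 2 # ascending; lam[k] is the largest

  solve_tridiag <- function(dd, ee, b) {
    nn <- length(dd)
    cp <- numeric(nn); dp <- numeric(nn)
    cp[1] <- ee[1] / dd[1]
    dp[1] <- b[1] / dd[1]
    for (i in 2:nn) {
      m <- dd[i] - ee[i - 1] * cp[i - 1]
      if (abs(m) < 1e-300) m <- 1e-300
      if (i < nn) cp[i] <- ee[i] / m
      dp[i] <- (b[i] - ee[i - 1] * dp[i - 1]) / m
    }
    x <- numeric(nn)
    x[nn] <- dp[nn]
    for (i in (nn - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
    x
  }

  V <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lj <- lam[k - j + 1] # j-th taper (1-based) pairs with j-th largest
    v <- sin(pi * j * (t0 + 1) / (n + 1)) # deterministic start vector
    for (it in 1:5) {
      v <- solve_tridiag(d - lj - 1e-8 * max(abs(lj), 1), e, v)
      if (j > 1) {
        prev <- V[, 1:(j - 1), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      v <- v / sqrt(sum(v^2))
    }
    if (j %% 2 == 1) {
      if (sum(v) < 0) v <- -v
    } else if (v[2] - v[1] < 0) {
      v <- -v
    }
    V[, j] <- v
  }
  .dpss_cache[[key]] <- V
  V
}

#' Multitaper power spectrum of one window
#'
#' Average of tapered periodograms over orthonormal Slepian tapers, scaled
#' as a one-sided density so that the integral of `power` over `freqs`
#' approximates the window variance (Parseval). The window is demeaned
#' before tapering.
#'
#' @param x Numeric signal window (uV).
#' @param rate Sampling rate in Hz.
#' @param time_halfbandwidth Time-halfbandwidth product (default 4, i.e.
#'   0.8 Hz resolution bandwidth for a 10 s window).
#' @param n_tapers Number of tapers (default 7 = `2 * 4 - 1`).
#' @param electrode_id,window_id Optional identifiers carried in the result.
#' @return An object of class `spectrum_estimate`: list with `freqs` (Hz),
#'   `power` (uV^2/Hz), `rate`, `n`, `electrode_id`, `window_id`, and the
#'   taper parameters.
#' @export
multitaper_spectrum <- function(x, rate, time_halfbandwidth = 4, n_tapers = 7,
                                electrode_id = NA_character_,
                                window_id = NA_integer_) {
  n <- length(x)
  V <- dpss_tapers(n, time_halfbandwidth, n_tapers)
  x <- x - mean(x)
  X <- stats::mvfft(V * x)
  nf <- floor(n / 2) + 1
  P <- Mod(X[1:nf, , drop = FALSE])^2
  S <- rowMeans(P) * 2 / rate
  S[1] <- S[1] / 2
  if (n %% 2 == 0) S[nf] <- S[nf] / 2
  structure(
    list(
      freqs = (0:(nf - 1)) * rate / n,
      power = S,
      rate = rate,
      n = n,
      time_halfbandwidth = time_halfbandwidth,
      n_tapers = n_tapers,
      electrode_id = electrode_id,
      window_id = window_id
    ),
    class = "spectrum_estimate"
  )
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectrum_estimate> %d bins to %.1f Hz (nw = %g, %d tapers)\n",
    length(x$freqs), max(x$freqs), x$time_halfbandwidth, x$n_tapers
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spectrum estimate into a tibble
#' @param x A `spectrum_estimate`.
#' @param ... Unused.
#' @return Tibble with columns `electrode_id`, `window_id`, `freq`, `power`.
#' @export
tidy.spectrum_estimate <- function(x, ...) {
  tibble::tibble(
    electrode_id = x$electrode_id,
    window_id = x$window_id,
    freq = x$freqs,
    power = x$power
  )
}
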
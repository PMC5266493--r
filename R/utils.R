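# Internal numerical helpers shared across modules.

#' Analytic-signal envelope
#'
#' Instantaneous amplitude of a real signal: the magnitude of the analytic
#' signal obtained by zeroing negative frequencies in the DFT.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @keywords internal
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Mean band power of a signal segment: mean squared value of the ideally
# band-limited component, computed in the frequency domain (Parseval).
# Inclusive band edges on the DFT grid.
fft_band_power <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * rate / n
  nf <- floor(n / 2) + 1
  sel <- which(f[1:nf] >= f_lo & f[1:nf] <= f_hi)
  if (!length(sel)) return(0)
  p <- Mod(X[sel])^2 / n^2
  # double interior bins to account for the conjugate half
  interior <- !(sel == 1L | (n %% 2 == 0 & sel == nf))
  sum(p * ifelse(interior, 2, 1))
}

# Maximal runs of TRUE in a logical vector -> matrix with columns start, end
# (1-based inclusive sample indices). Zero-row matrix when no run.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Linear-phase FIR band-pass design (Hamming window method via signal::fir1).
# Transition width follows the convention: 1 Hz for bands starting below
# 10 Hz, 2 Hz otherwise.
design_bandpass <- function(band, rate, transition_hz = NULL) {
  band <- as_band(band)
  if (band$f_hi >= rate / 2) {
    stop("band upper edge must lie below the Nyquist frequency", call. = FALSE)
  }
  if (is.null(transition_hz)) transition_hz <- if (band$f_lo < 10) 1 else 2
  ord <- ceiling(3.3 * rate / transition_hz)
  if (ord %% 2 == 1) ord <- ord + 1 # even order -> odd-length symmetric FIR
  lo <- max(band$f_lo - transition_hz / 2, 0.01)
  hi <- min(band$f_hi + transition_hz / 2, rate / 2 * 0.999)
  h <- signal::fir1(ord, c(lo, hi) / (rate / 2), type = "pass")
  list(h = as.numeric(h), order = ord, length = ord + 1L)
}

# Zero-phase FIR filtering: FFT convolution with a symmetric odd-length
# kernel, keeping the centred part so the group delay cancels exactly.
# Padded to a power of two -- raw convolution lengths can have large prime
# factors that make the FFT orders of magnitude slower.
filter_zerophase <- function(x, h) {
  n <- length(x)
  L <- length(h)
  m <- stats::nextn(n + L - 1, 2)
  X <- stats::fft(c(x, numeric(m - n)))
  H <- stats::fft(c(h, numeric(m - L)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / m
  off <- (L - 1) / 2
  y[(off + 1):(off + n)]
}

# trapezoidal integral on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}
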
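#' Define a frequency band
#'
#' A band is a named frequency interval with a centre frequency used for
#' cycle-length arithmetic (burst durations, coherence read-out frequency).
#'
#' @param name Band name, e.g. `"theta"`.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @param f_center Centre frequency in Hz; defaults to the midpoint.
#'
#' @return An object of class `band_def`: a list with elements `name`,
#'   `f_lo`, `f_hi`, `f_center`.
#' @export
#' @examples
#' band_definition("theta", 4, 8)
band_definition <- function(name, f_lo, f_hi, f_center = (f_lo + f_hi) / 2) {
  stopifnot(is.character(name), length(name) == 1)
  if (!(is.numeric(f_lo) && is.numeric(f_hi) && f_lo > 0 && f_lo < f_hi)) {
    stop("band edges must satisfy 0 < f_lo < f_hi", call. = FALSE)
  }
  structure(
    list(name = name, f_lo = f_lo, f_hi = f_hi, f_center = f_center),
    class = "band_def"
  )
}

#' Canonical analysis bands
#'
#' The four bands used throughout the package: theta (4-8 Hz) and beta
#' (15-35 Hz) for REM oscillation analysis, the sleep-spindle band
#' (11-16 Hz) and delta (0.5-4 Hz) for staging features.
#'
#' @return A named list of [band_definition()] objects.
#' @export
canonical_bands <- function() {
  list(
    theta   = band_definition("theta", 4, 8),
    beta    = band_definition("beta", 15, 35),
    spindle = band_definition("spindle", 11, 16),
    delta   = band_definition("delta", 0.5, 4)
  )
}

#' Resolve a band argument
#'
#' Accepts either a `band_def` object or the name of a canonical band.
#'
#' @param band A `band_def` or a character name from [canonical_bands()].
#' @return A `band_def`.
#' @export
as_band <- function(band) {
  if (inherits(band, "band_def")) return(band)
  if (is.character(band) && length(band) == 1) {
    bands <- canonical_bands()
    if (band %in% names(bands)) return(bands[[band]])
    stop("unknown band name: ", band, call. = FALSE)
  }
  stop("`band` must be a band_def or a canonical band name", call. = FALSE)
}

#' @export
print.band_def <- function(x, ...) {
  cat(sprintf(
    "<band> %s: %g-%g Hz (center %g Hz)\n",
    x$name, x$f_lo, x$f_hi, x$f_center
  ))
  invisible(x)
}
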
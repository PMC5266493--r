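# Minimal EDF (European Data Format, 16-bit) reader and writer. No EDF
# package ships with the R installation this package targets, so the
# format's fixed-width ASCII header and little-endian int16 data records
# are handled directly here. Continuous recordings only (no annotations);
# one-second data records.

pad_field <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Signals are scaled to the 16-bit digital range per channel (physical
#' range = observed signal range), so a round trip preserves each signal
#' to within one quantisation step.
#'
#' @param rec A [recording()]. The sampling rate must be a whole number
#'   (samples are stored in one-second records).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sample_rate
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate", call. = FALSE)
  ns <- n_channels(rec)
  n_rec <- floor(ncol(rec$signals) / fs)
  if (n_rec < 1) stop("recording shorter than one data record", call. = FALSE)
  phys_min <- apply(rec$signals, 1, min)
  phys_max <- apply(rec$signals, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(pad_field(rec$channels$label, 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(pad_field(sprintf("%.6g", phys_min), 8), collapse = ""),
    paste(pad_field(sprintf("%.6g", phys_max), 8), collapse = ""),
    paste(rep(pad_field("-32768", 8), ns), collapse = ""),
    paste(rep(pad_field("32767", 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(sig_hdr, con, eos = NULL)
  gain <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_rec)) {
    sel <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((rec$signals[ch, sel] - phys_min[ch]) / gain[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80); rec_id <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  hdr_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); transducer <- fld(80); dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  prefilter <- fld(80)
  spr <- as.integer(fld(8)); fld(32)
  list(
    n_rec = n_rec, rec_dur = rec_dur, ns = ns, labels = labels,
    phys_min = phys_min, phys_max = phys_max,
    dig_min = dig_min, dig_max = dig_max, spr = spr
  )
}

#' Read an EDF file into a signal matrix
#'
#' @param path EDF file path.
#' @return List with `signals` (channels x samples, physical units),
#'   `labels`, `sample_rates` (per channel, Hz).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  sig <- lapply(seq_len(h$ns), function(i) numeric(h$n_rec * h$spr[i]))
  gain <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  for (r in seq_len(h$n_rec)) {
    for (ch in seq_len(h$ns)) {
      dig <- readBin(con, "integer", n = h$spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      sig[[ch]][((r - 1) * h$spr[ch] + 1):(r * h$spr[ch])] <-
        (dig - h$dig_min[ch]) * gain[ch] + h$phys_min[ch]
    }
  }
  list(
    signals = do.call(rbind, sig),
    labels = h$labels,
    sample_rates = h$spr / h$rec_dur
  )
}

#' Read a recording from an EDF file with a montage table
#'
#' Attaches channel metadata to the EDF's signals. Only channels named in
#' the montage are kept; a montage label absent from the file is a hard
#' error naming the label, and mixed per-channel sampling rates among the
#' selected channels are rejected.
#'
#' @param path EDF file path.
#' @param montage_spec Data frame of channel metadata (see [recording()]);
#'   may also be the path of a montage CSV.
#' @return A [recording()].
#' @export
read_recording <- function(path, montage_spec) {
  if (is.character(montage_spec)) montage_spec <- read_montage_csv(montage_spec)
  montage_spec <- tibble::as_tibble(montage_spec)
  edf <- read_edf(path)
  if (nrow(montage_spec) == 0) {
    warning("empty montage: recording has zero analyzable channels")
    return(recording(
      matrix(numeric(0), 0, ncol(edf$signals)),
      if (length(unique(edf$sample_rates))) edf$sample_rates[1] else 1,
      montage_spec
    ))
  }
  idx <- match(montage_spec$label, edf$labels)
  if (anyNA(idx)) {
    stop("montage label(s) not present in EDF file: ",
         paste(montage_spec$label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  rates <- edf$sample_rates[idx]
  if (length(unique(rates)) > 1) {
    stop("selected channels have differing sampling rates", call. = FALSE)
  }
  recording(edf$signals[idx, , drop = FALSE], rates[1], montage_spec)
}

#' Read / write a montage CSV
#'
#' Columns: `label`, `modality`, `region`, `shaft_id`, `contact_index`,
#' `gray_matter`, `excluded`.
#'
#' @param path CSV path.
#' @param montage Data frame of channel metadata.
#' @return `read_montage_csv()`: a tibble; `write_montage_csv()`: `path`,
#'   invisibly.
#' @export
read_montage_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    label = readr::col_character(),
                    modality = readr::col_character(),
                    region = readr::col_character(),
                    shaft_id = readr::col_character(),
                    contact_index = readr::col_integer(),
                    gray_matter = readr::col_logical(),
                    excluded = readr::col_logical()
                  ))
}

#' @rdname read_montage_csv
#' @export
write_montage_csv <- function(montage, path) {
  readr::write_csv(tibble::as_tibble(montage), path)
  invisible(path)
}
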
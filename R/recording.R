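#' Construct a multichannel recording
#'
#' The central data container: a channels-by-samples signal matrix (in
#' microvolts) with one metadata row per channel. Depth contacts carry a
#' shaft identifier and a contact index (1 = most distal) so that bipolar
#' derivations between adjacent contacts can be formed with
#' [make_bipolar()].
#'
#' @param signals Numeric matrix, channels x samples, in uV.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param channels Data frame of channel metadata with columns `label`,
#'   `modality` (one of depth, scalp_eeg, emg, eog_left, eog_right),
#'   `region` (DLPFC, ACC, IFG, MTG, other, unknown), `shaft_id`,
#'   `contact_index`, `gray_matter`, `excluded`. Missing columns are filled
#'   with defaults (`region = "unknown"`, `gray_matter = TRUE`,
#'   `excluded = FALSE`).
#' @param start_offset_s Seconds from session start to the first sample.
#'
#' @return An object of class `recording`.
#' @export
recording <- function(signals, sample_rate, channels, start_offset_s = 0) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  stopifnot(is.matrix(signals), is.numeric(signals))
  if (!(is.numeric(sample_rate) && length(sample_rate) == 1 && sample_rate > 0)) {
    stop("sample_rate must be a positive number", call. = FALSE)
  }
  channels <- normalize_channels(channels, n = nrow(signals))
  structure(
    list(
      signals = signals,
      sample_rate = sample_rate,
      channels = channels,
      start_offset_s = start_offset_s
    ),
    class = "recording"
  )
}

valid_modalities <- c("depth", "scalp_eeg", "emg", "eog_left", "eog_right")
valid_regions <- c("DLPFC", "ACC", "IFG", "MTG", "other", "unknown")

normalize_channels <- function(channels, n) {
  channels <- tibble::as_tibble(channels)
  if (nrow(channels) != n) {
    stop("channel metadata rows (", nrow(channels),
         ") must match signal rows (", n, ")", call. = FALSE)
  }
  if (!"label" %in% names(channels)) {
    stop("channel metadata must contain a `label` column", call. = FALSE)
  }
  if (anyDuplicated(channels$label)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  defaults <- list(
    modality = "depth", region = "unknown", shaft_id = NA_character_,
    contact_index = NA_integer_, gray_matter = TRUE, excluded = FALSE
  )
  for (col in names(defaults)) {
    if (!col %in% names(channels)) channels[[col]] <- defaults[[col]]
  }
  bad <- setdiff(unique(channels$modality), valid_modalities)
  if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(channels$region), valid_regions)
  if (length(bad)) stop("unknown region: ", paste(bad, collapse = ", "), call. = FALSE)
  channels$contact_index <- as.integer(channels$contact_index)
  # contact_index unique within a shaft
  depth <- channels[channels$modality == "depth" & !is.na(channels$shaft_id), ]
  if (nrow(depth)) {
    dup <- stats::aggregate(contact_index ~ shaft_id, depth,
                            function(ci) anyDuplicated(ci[!is.na(ci)]) > 0)
    if (any(dup$contact_index)) {
      stop("contact_index must be unique within shaft: ",
           paste(dup$shaft_id[dup$contact_index], collapse = ", "), call. = FALSE)
    }
  }
  channels[c("label", "modality", "region", "shaft_id", "contact_index",
             "gray_matter", "excluded",
             setdiff(names(channels),
                     c("label", "modality", "region", "shaft_id",
                       "contact_index", "gray_matter", "excluded")))]
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channel(s), %.1f s at %g Hz (offset %.1f s)\n",
    n_channels(x), duration_s(x), x$sample_rate, x$start_offset_s
  ))
  print(dplyr::count(x$channels, .data$modality))
  invisible(x)
}

#' Number of channels in a recording
#' @param rec A [recording()].
#' @return Integer.
#' @export
n_channels <- function(rec) nrow(rec$signals)

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Numeric seconds.
#' @export
duration_s <- function(rec) ncol(rec$signals) / rec$sample_rate

#' Extract one channel's signal by label
#' @param rec A [recording()].
#' @param label Channel label.
#' @return Numeric vector.
#' @export
channel_signal <- function(rec, label) {
  i <- match(label, rec$channels$label)
  if (is.na(i)) stop("no channel labelled '", label, "'", call. = FALSE)
  rec$signals[i, ]
}

# first channel of a given modality, hard error naming the modality
modality_signal <- function(rec, modality) {
  i <- which(rec$channels$modality == modality)
  if (!length(i)) {
    stop("recording has no channel of modality '", modality, "'", call. = FALSE)
  }
  rec$signals[i[1], ]
}

#' Extract a sample-aligned time slice of a recording
#'
#' The slice covers `[start_s, end_s)`; the start index is
#' `round(start_s * rate)` (0-based), half-open on the right, so abutting
#' slices partition the recording exactly.
#'
#' @param rec A [recording()].
#' @param start_s,end_s Slice bounds in seconds, `0 <= start_s < end_s <=`
#'   duration.
#' @return A [recording()] whose `start_offset_s` is advanced by `start_s`.
#' @export
slice_interval <- function(rec, start_s, end_s) {
  dur <- duration_s(rec)
  if (!(start_s >= 0 && start_s < end_s && end_s <= dur + 1e-9)) {
    stop(sprintf("interval [%g, %g) out of range for a %g s recording",
                 start_s, end_s, dur), call. = FALSE)
  }
  i0 <- round(start_s * rec$sample_rate)
  i1 <- round(end_s * rec$sample_rate)
  i1 <- min(i1, ncol(rec$signals))
  recording(
    rec$signals[, (i0 + 1):i1, drop = FALSE],
    rec$sample_rate,
    rec$channels,
    start_offset_s = rec$start_offset_s + i0 / rec$sample_rate
  )
}

#' Build bipolar derivations from depth contacts
#'
#' Forms one derived channel per pair of adjacent contacts (consecutive
#' `contact_index`) on the same shaft, as the deeper (lower-index) contact
#' minus the shallower one. Pairs in which either contact is flagged
#' `excluded` are dropped. With `region_restrict = TRUE`, pairs are kept
#' only when both contacts share a defined region and at least one lies in
#' gray matter, so that derived activity can be attributed to a single
#' region.
#'
#' @param rec A [recording()] containing depth channels with populated
#'   `shaft_id` and `contact_index`.
#' @param region_restrict Apply the same-region / gray-matter filter.
#' @return A [recording()] of derived channels. Each derived channel's
#'   metadata records both parent labels (`parent_a`, `parent_b`), the
#'   shared region, and the deeper contact's index. Non-depth channels are
#'   not carried over.
#' @export
make_bipolar <- function(rec, region_restrict = FALSE) {
  ch <- rec$channels
  depth <- which(ch$modality == "depth")
  if (length(depth) && anyNA(ch$contact_index[depth])) {
    stop("depth channels must have contact_index populated", call. = FALSE)
  }
  out_sig <- list()
  out_meta <- list()
  for (shaft in unique(stats::na.omit(ch$shaft_id[depth]))) {
    idx <- depth[which(ch$shaft_id[depth] == shaft)]
    idx <- idx[order(ch$contact_index[idx])]
    if (length(idx) < 2) next
    for (k in seq_len(length(idx) - 1)) {
      a <- idx[k]; b <- idx[k + 1]
      if (ch$contact_index[b] != ch$contact_index[a] + 1L) next # not adjacent
      if (ch$excluded[a] || ch$excluded[b]) next
      region <- if (ch$region[a] == ch$region[b]) ch$region[a] else "unknown"
      if (region_restrict) {
        if (region == "unknown") next
        if (!(ch$gray_matter[a] || ch$gray_matter[b])) next
      }
      lab <- paste0(ch$label[a], "-", ch$label[b])
      out_sig[[lab]] <- rec$signals[a, ] - rec$signals[b, ]
      out_meta[[lab]] <- tibble::tibble(
        label = lab, modality = "depth", region = region,
        shaft_id = shaft, contact_index = ch$contact_index[a],
        gray_matter = ch$gray_matter[a] || ch$gray_matter[b],
        excluded = FALSE,
        parent_a = ch$label[a], parent_b = ch$label[b]
      )
    }
  }
  if (!length(out_sig)) {
    return(recording(
      matrix(numeric(0), nrow = 0, ncol = ncol(rec$signals)),
      rec$sample_rate,
      tibble::tibble(
        label = character(), modality = character(), region = character(),
        shaft_id = character(), contact_index = integer(),
        gray_matter = logical(), excluded = logical(),
        parent_a = character(), parent_b = character()
      ),
      rec$start_offset_s
    ))
  }
  recording(
    do.call(rbind, out_sig),
    rec$sample_rate,
    dplyr::bind_rows(out_meta),
    rec$start_offset_s
  )
}
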
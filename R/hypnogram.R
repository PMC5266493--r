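stage_levels <- c("W", "N1", "N2", "N3", "REM", "other")

#' Construct a hypnogram
#'
#' Epoch-wise sleep-stage labels at a fixed epoch length (30 s by
#' convention). Labels are W, N1, N2, N3, REM; `other` is allowed for
#' classifier output that only distinguishes REM from the rest.
#'
#' @param labels Character vector of stage labels, one per epoch.
#' @param epoch_length_s Epoch length in seconds.
#' @return A tibble of class `hypnogram` with columns `epoch` (1-based) and
#'   `stage`, and an `epoch_length_s` attribute.
#' @export
hypnogram <- function(labels, epoch_length_s = 30) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), stage_levels)
  if (length(bad)) stop("unknown stage label: ", paste(bad, collapse = ", "), call. = FALSE)
  out <- tibble::tibble(
    epoch = seq_along(labels),
    stage = factor(labels, levels = stage_levels)
  )
  attr(out, "epoch_length_s") <- epoch_length_s
  class(out) <- c("hypnogram", class(out))
  out
}

#' Epoch length of a hypnogram
#' @param hyp A [hypnogram()].
#' @return Seconds per epoch.
#' @export
epoch_length_s <- function(hyp) attr(hyp, "epoch_length_s")

#' Select long uninterrupted REM episodes
#'
#' Returns the maximal runs of consecutive REM-labelled epochs whose total
#' duration strictly exceeds `min_duration_s` (default 5 min). A run
#' interrupted by any non-REM epoch is split and each part judged on its
#' own. Episodes are returned untrimmed; the first and last 10 s of each
#' episode are additionally required to fall inside REM-labelled epochs
#' (automatic for 30 s epochs, checked for non-default epoch lengths).
#'
#' @param hyp A [hypnogram()].
#' @param min_duration_s Minimum episode duration in seconds (strict).
#' @return Tibble with columns `start_s`, `end_s`, `n_epochs`, sorted and
#'   disjoint.
#' @export
select_rem_episodes <- function(hyp, min_duration_s = 300) {
  len <- epoch_length_s(hyp)
  mask <- hyp$stage == "REM"
  runs <- logical_runs(mask)
  out <- tibble::tibble(
    start_s = unname((runs[, "start"] - 1) * len),
    end_s = unname(runs[, "end"] * len),
    n_epochs = unname(runs[, "end"] - runs[, "start"] + 1L)
  )
  out <- out[out$end_s - out$start_s > min_duration_s, , drop = FALSE]
  # purity of the first and last 10 s: both must lie within REM epochs
  if (nrow(out)) {
    ok <- vapply(seq_len(nrow(out)), function(i) {
      e0 <- floor(out$start_s[i] / len) + 1
      e0b <- floor((out$start_s[i] + 10 - 1e-9) / len) + 1
      e1 <- floor((out$end_s[i] - 1e-9) / len) + 1
      e1b <- floor((out$end_s[i] - 10) / len) + 1
      all(mask[e0:e0b]) && all(mask[e1b:e1])
    }, logical(1))
    out <- out[ok, , drop = FALSE]
  }
  out
}

#' Write / read a hypnogram as CSV
#'
#' Two-column CSV (`epoch_index`, `label`) preceded by a comment line
#' declaring the epoch length, e.g. `# epoch_length_s: 30`.
#'
#' @param hyp A [hypnogram()].
#' @param path File path.
#' @return `write_hypnogram_csv()` returns `path` invisibly;
#'   `read_hypnogram_csv()` returns a [hypnogram()].
#' @export
write_hypnogram_csv <- function(hyp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epoch_length_s: %g", epoch_length_s(hyp)), con)
  writeLines("epoch_index,label", con)
  writeLines(sprintf("%d,%s", hyp$epoch, as.character(hyp$stage)), con)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  first <- readLines(path, n = 1)
  len <- 30
  if (grepl("^#", first)) {
    m <- regmatches(first, regexpr("[0-9.]+", first))
    if (length(m)) len <- as.numeric(m)
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tab <- tab[order(tab$epoch_index), ]
  hypnogram(tab$label, epoch_length_s = len)
}
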
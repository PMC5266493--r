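# Shared fixtures and small oracles used across the test files.

# montage tibble for one shaft of depth contacts
shaft_montage <- function(n, shaft = "A", region = "DLPFC",
                          gray = rep(TRUE, n), excluded = rep(FALSE, n)) {
  tibble::tibble(
    label = paste0(shaft, seq_len(n)),
    modality = "depth",
    region = rep(region, length.out = n),
    shaft_id = shaft,
    contact_index = seq_len(n),
    gray_matter = gray,
    excluded = excluded
  )
}

# brute-force oracle for bipolar derivation filtering: enumerate every
# adjacent same-shaft pair and apply the three filters independently of
# make_bipolar()
bipolar_oracle <- function(channels, region_restrict) {
  keep <- list()
  depth <- channels[channels$modality == "depth" & !is.na(channels$shaft_id), ]
  for (shaft in unique(depth$shaft_id)) {
    sc <- depth[depth$shaft_id == shaft, ]
    for (ci in sort(sc$contact_index)) {
      a <- sc[sc$contact_index == ci, ]
      b <- sc[sc$contact_index == ci + 1, ]
      if (nrow(a) != 1 || nrow(b) != 1) next
      if (a$excluded || b$excluded) next
      if (region_restrict) {
        if (a$region != b$region || a$region == "unknown") next
        if (!(a$gray_matter || b$gray_matter)) next
      }
      keep[[length(keep) + 1]] <- paste0(a$label, "-", b$label)
    }
  }
  unlist(keep)
}

# interval Jaccard overlap
jaccard_interval <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  if (inter == 0) return(0)
  inter / (max(a1, b1) - min(a0, b0))
}

# best Jaccard of one truth interval against a table of detected events
best_jaccard <- function(start_s, end_s, events) {
  if (nrow(events) == 0) return(0)
  max(vapply(seq_len(nrow(events)), function(k) {
    jaccard_interval(start_s, end_s, events$start_s[k], events$end_s[k])
  }, numeric(1)))
}

# compact synthetic night for pipeline tests: 33 min with one 5.5 min REM
# block (66 epochs, REM fraction ~17%)
small_scenario <- function(seed = 1) {
  scenario_spec(
    stages = tibble::tibble(
      stage = c("W", "N2", "N3", "REM", "N2"),
      duration_s = c(120, 600, 480, 330, 450)
    ),
    seed = seed
  )
}
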
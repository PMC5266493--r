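test_that("band definitions validate their edges and resolve by name", {
  b <- band_definition("theta", 4, 8)
  expect_equal(b$f_center, 6)
  expect_error(band_definition("bad", 8, 4), "f_lo < f_hi")
  expect_error(band_definition("bad", 0, 4), "f_lo < f_hi")
  expect_equal(as_band("beta")$f_hi, 35)
  expect_error(as_band("gamma"), "unknown band")
  cb <- canonical_bands()
  expect_equal(cb$spindle$f_lo, 11)
  expect_equal(cb$delta$f_hi, 4)
})

test_that("recording constructor validates metadata", {
  sig <- matrix(rnorm(20), nrow = 2)
  ch <- shaft_montage(2)
  rec <- recording(sig, 500, ch)
  expect_equal(n_channels(rec), 2)
  expect_error(recording(sig, 500, ch[1, ]), "must match signal rows")
  expect_error(recording(sig, -1, ch), "positive")
  dup <- ch; dup$contact_index <- c(1L, 1L)
  expect_error(recording(sig, 500, dup), "unique within shaft")
  badmod <- ch; badmod$modality <- "meg"
  expect_error(recording(sig, 500, badmod), "unknown modality")
})

test_that("slice_interval is sample-aligned and partitions exactly", {
  rec <- recording(matrix(rnorm(2 * 10000), nrow = 2), 500, shaft_montage(2))
  s <- slice_interval(rec, 10, 20)
  expect_equal(ncol(s$signals), 5000)
  expect_equal(s$start_offset_s, 10)
  # identity slice
  full <- slice_interval(rec, 0, duration_s(rec))
  expect_identical(full$signals, rec$signals)
  # abutting slices concatenate to the containing slice
  a <- slice_interval(rec, 0, 10)
  b <- slice_interval(rec, 10, 20)
  expect_identical(cbind(a$signals, b$signals), slice_interval(rec, 0, 20)$signals)
  expect_equal(b$sample_rate, rec$sample_rate)
  expect_error(slice_interval(rec, -1, 5), "out of range")
  expect_error(slice_interval(rec, 15, 25), "out of range")
})

test_that("an intact single-region shaft yields one derivation per adjacent pair", {
  n <- 8
  rec <- recording(matrix(rnorm(8 * 100), nrow = 8), 500, shaft_montage(8))
  bip <- make_bipolar(rec, region_restrict = TRUE)
  expect_equal(n_channels(bip), 7)
  # polarity: deeper (lower index) minus shallower
  expect_equal(bip$signals[1, ], rec$signals[1, ] - rec$signals[2, ])
  expect_equal(bip$channels$parent_a[1], "A1")
  expect_equal(bip$channels$parent_b[1], "A2")
  # single-contact shaft contributes nothing
  one <- recording(matrix(rnorm(100), nrow = 1), 500, shaft_montage(1))
  expect_equal(n_channels(make_bipolar(one)), 0)
})

test_that("region and exclusion filters match the brute-force pair enumeration", {
  # 8-contact shaft: contacts 1-3 ACC, 4-8 other, contact 5 excluded
  ch <- shaft_montage(8)
  ch$region <- c(rep("ACC", 3), rep("other", 5))
  ch$excluded[5] <- TRUE
  rec <- recording(matrix(rnorm(8 * 50), nrow = 8), 500, ch)
  got <- make_bipolar(rec, region_restrict = TRUE)$channels$label
  expect_setequal(got, bipolar_oracle(ch, TRUE))
  # property test over random montages
  withr::with_seed(42, {
    for (rep in 1:25) {
      n_shafts <- sample(1:3, 1)
      ch <- dplyr::bind_rows(lapply(seq_len(n_shafts), function(s) {
        n <- sample(1:8, 1)
        shaft_montage(
          n, shaft = LETTERS[s],
          region = sample(c("DLPFC", "ACC", "other", "unknown"), n, replace = TRUE),
          gray = sample(c(TRUE, FALSE), n, replace = TRUE),
          excluded = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.2, .8))
        )
      }))
      rec <- recording(matrix(rnorm(nrow(ch) * 20), nrow = nrow(ch)), 500, ch)
      for (rr in c(TRUE, FALSE)) {
        got <- make_bipolar(rec, region_restrict = rr)$channels$label
        want <- bipolar_oracle(ch, rr)
        expect_setequal(got, if (is.null(want)) character(0) else want)
      }
    }
  })
})

test_that("missing contact_index on depth channels is a hard error", {
  ch <- shaft_montage(3)
  ch$contact_index[2] <- NA_integer_
  rec <- recording(matrix(rnorm(3 * 20), nrow = 3), 500, ch)
  expect_error(make_bipolar(rec), "contact_index")
})

test_that("EDF round trip preserves signals to within 16-bit quantisation", {
  withr::with_seed(7, {
    sig <- matrix(rnorm(3 * 1000, sd = 50), nrow = 3)
  })
  rec <- recording(sig, 500, shaft_montage(3))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_recording(f, rec$channels)
  expect_equal(back$sample_rate, 500)
  qstep <- max(apply(sig, 1, function(x) diff(range(x)))) / 65535
  expect_lt(max(abs(back$signals - rec$signals)), qstep)
  expect_equal(back$channels$label, rec$channels$label)
})

test_that("montage errors and the empty montage are handled", {
  rec <- recording(matrix(rnorm(2 * 1000), nrow = 2), 500, shaft_montage(2))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  bad <- shaft_montage(2)
  bad$label[2] <- "NOPE"
  expect_error(read_recording(f, bad), "NOPE")
  expect_warning(empty <- read_recording(f, shaft_montage(0)), "empty montage")
  expect_equal(n_channels(empty), 0)
})

test_that("montage and hypnogram CSVs round trip", {
  ch <- shaft_montage(4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_montage_csv(ch, f)
  back <- read_montage_csv(f)
  expect_equal(back$label, ch$label)
  expect_equal(back$contact_index, ch$contact_index)

  hyp <- hypnogram(c("W", "N2", "REM", "REM", "N3"), epoch_length_s = 30)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram_csv(hyp, f2)
  back2 <- read_hypnogram_csv(f2)
  expect_equal(as.character(back2$stage), as.character(hyp$stage))
  expect_equal(epoch_length_s(back2), 30)
})
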
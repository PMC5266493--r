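test_that("the envelope of a pure sinusoid equals its amplitude", {
  t <- (0:29999) / 500
  x <- 3.2 * sin(2 * pi * 25 * t)
  env <- band_envelope(x, 500, "beta")
  core <- !attr(env, "edge")
  expect_equal(mean(env[core]), 3.2, tolerance = 0.02)
  expect_lt(max(abs(env[core] - 3.2) / 3.2), 0.02)
  # zero signal -> zero envelope
  expect_equal(max(band_envelope(numeric(20000), 500, "beta")), 0)
})

test_that("the envelope tracks a known burst amplitude window", {
  fs <- 500
  bc <- gen_burst_channel(60, fs, "beta", bursts_per_min = 2, n_cycles = 20,
                          snr = 2000, seed = 3)
  env <- band_envelope(bc$signal, fs, "beta")
  b <- bc$bursts[1, ]
  n0 <- round(b$start_s * fs); n1 <- round(b$end_s * fs)
  w <- remosc:::burst_window(n1 - n0)
  rel_err <- abs(env[(n0 + 1):n1] - bc$amplitude * w) / bc$amplitude
  # the filter smears the ramp corners; the flat top must track closely
  expect_lt(max(rel_err[w > 0.999]), 0.1)
  # overall the envelope follows the amplitude window
  expect_gt(stats::cor(env[(n0 + 1):n1], w), 0.95)
})

test_that("too-short signals and infeasible bands error out", {
  expect_error(band_envelope(rnorm(100), 500, "beta"), "too short")
  expect_error(band_envelope(rnorm(10000), 60, "beta"), "Nyquist")
})

test_that("a constant envelope yields no bursts", {
  expect_equal(nrow(detect_bursts(rep(2, 10000), 500, "beta")), 0)
})

test_that("a single injected burst is found once with tight boundaries", {
  fs <- 500
  hits <- 0; errs <- c()
  for (s in 1:10) {
    bc <- gen_burst_channel(60, fs, "beta", bursts_per_min = 1, n_cycles = 4,
                            snr = 10, seed = 40 + s)
    env <- band_envelope(bc$signal, fs, "beta")
    ev <- detect_bursts(env, fs, "beta")
    tr <- bc$bursts[1, ]
    ov <- ev[ev$end_s > tr$start_s & ev$start_s < tr$end_s, ]
    if (nrow(ov) == 1) {
      hits <- hits + 1
      errs <- c(errs, abs(ov$start_s - tr$start_s), abs(ov$end_s - tr$end_s))
    }
  }
  expect_gte(hits, 9)
  # boundary error stays within the envelope-ramp crossing scale
  expect_lt(stats::median(errs), 0.04)
  expect_lt(max(errs), 0.08)
})

test_that("bursts shorter than the cycle criterion are rejected", {
  fs <- 500
  band <- as_band("beta")
  # 1.5-cycle burst = 60 ms at 25 Hz; keep a clean synthetic envelope
  env <- rep(0.1, 30000)
  n <- round(1.5 / band$f_center * fs)
  env[10000:(10000 + n - 1)] <- 5
  expect_equal(nrow(detect_bursts(env, fs, band)), 0)
  # the same excursion at 2.5 cycles passes
  n2 <- round(2.5 / band$f_center * fs)
  env2 <- rep(0.1, 30000)
  env2[10000:(10000 + n2 - 1)] <- 5
  expect_equal(nrow(detect_bursts(env2, fs, band)), 1)
})

test_that("detection count is monotone non-increasing in the threshold", {
  # isolated 3-cycle excursions of graded height: raising the threshold can
  # only drop whole excursions
  withr::with_seed(9, {
    env <- abs(rnorm(50000, sd = 0.1)) + 0.2
    heights <- seq(2, 12, length.out = 10)
    starts <- seq(2000, 47000, length.out = 10)
    for (i in 1:10) env[starts[i] + 0:59] <- heights[i]
  })
  counts <- vapply(c(0.5, 1, 2, 3, 4, 6, 10), function(th) {
    nrow(detect_bursts(env, 500, "beta", threshold_sd = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[length(counts)])
})

test_that("sub-cycle gaps are merged before the duration test", {
  fs <- 500
  band <- as_band("beta") # one cycle at 25 Hz = 40 ms = 20 samples
  env <- rep(0.1, 30000)
  # two 50 ms runs separated by a 20 ms dip: one 120 ms burst after merging
  env[10000:10024] <- 5
  env[10035:10059] <- 5
  merged <- detect_bursts(env, fs, band)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$end_s - merged$start_s, 0.12, ignore_attr = TRUE)
  split <- detect_bursts(env, fs, band, merge_gap_cycles = 0)
  expect_equal(nrow(split), 0) # each fragment alone is under 2 cycles
})

test_that("the burst raster marks exactly the overlapped bins", {
  ev <- tibble::tibble(electrode_id = "e1", band = "beta",
                       start_s = 10.05, end_s = 10.21, peak_power = 1)
  m <- burst_raster(ev, electrode_ids = c("e1", "e2"), start_s = 0,
                    end_s = 20, bin_s = 1)
  expect_equal(dim(m), c(2, 20))
  expect_equal(which(m["e1", ]), 11) # the bin covering 10-11 s
  expect_false(any(m["e2", ]))
  # no bursts -> all-false
  none <- burst_raster(ev[0, ], electrode_ids = "e1", start_s = 0, end_s = 5)
  expect_false(any(none))
})
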
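test_that("window powers and degenerate inputs behave", {
  w2 <- window_2s(tibble::tibble(start_s = 0, end_s = 10))
  p <- window_envelope_power(rep(3, 5000), 500, w2)
  expect_equal(p$power, rep(9, 5))
  expect_equal(nrow(window_envelope_power(numeric(0), 500, w2[0, ])), 0)
  # a burst confined to window 3 makes it the maximum
  env <- rep(0.1, 5000)
  env[2200:2600] <- 4
  p <- window_envelope_power(env, 500, w2)
  expect_equal(which.max(p$power), 3)
})

test_that("joint top-quartile selection matches percentile arithmetic", {
  expect_equal(select_joint_top_quartile(1:100, 1:100), 76:100)
  # anti-correlated rankings: verified against brute-force intersection
  a <- 1:100; b <- 100:1
  got <- select_joint_top_quartile(a, b)
  want <- intersect(which(a >= stats::quantile(a, 0.75)),
                    which(b >= stats::quantile(b, 0.75)))
  expect_equal(got, want)
  expect_lte(length(got), 2)
  # all-equal powers: every window reaches its own 75th percentile
  expect_equal(select_joint_top_quartile(rep(2, 12), rep(5, 12)), 1:12)
  expect_error(select_joint_top_quartile(1:5, 1:5), ">= 8")
})

test_that("window_crosscov exchange is exactly antisymmetric", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      d <- abs(rnorm(600)); a <- abs(rnorm(600))
      cc1 <- window_crosscov(d, a, 500, max_lag_ms = 100)
      cc2 <- window_crosscov(a, d, 500, max_lag_ms = 100)
      expect_equal(cc1$ccov, rev(cc2$ccov), tolerance = 1e-12)
    }
  })
})

test_that("the sign convention puts the leading channel at positive lag", {
  withr::with_seed(12, d <- abs(rnorm(2000)) + sin(2 * pi * (1:2000) / 300))
  k <- 10 # a(t) = d(t - 20 ms): first argument leads by 20 ms
  a <- c(rep(d[1], k), d[1:(2000 - k)])
  cc <- window_crosscov(d, a, 500, max_lag_ms = 100)
  expect_equal(cc$lag_ms[which.max(cc$ccov)], 20)
  # autocovariance peaks at zero
  cc0 <- window_crosscov(d, d, 500, max_lag_ms = 100)
  expect_equal(cc0$lag_ms[which.max(cc0$ccov)], 0)
})

test_that("degenerate windows and lag bounds are flagged", {
  cc <- window_crosscov(rep(1, 500), rnorm(500), 500, 100)
  expect_true(attr(cc, "degenerate"))
  expect_equal(unique(cc$ccov), 0)
  expect_error(window_crosscov(rnorm(100), rnorm(100), 500, 200),
               "half the window")
})

test_that("null envelope cross-covariance shrinks with window length", {
  withr::with_seed(13, {
    m1 <- mean(replicate(20, {
      max(abs(window_crosscov(abs(rnorm(250)), abs(rnorm(250)), 500, 100)$ccov))
    }))
    m2 <- mean(replicate(20, {
      max(abs(window_crosscov(abs(rnorm(2000)), abs(rnorm(2000)), 500, 100)$ccov))
    }))
  })
  expect_lt(m2, m1)
})

test_that("averaging is pointwise and linear", {
  base <- list(lag_ms = seq(-100, 100, by = 2), n_windows_used = 1,
               pair_id = "p", band = "theta")
  f1 <- structure(c(base, list(ccov = sin(base$lag_ms / 30))),
                  class = "crosscov_result")
  f2 <- structure(c(base, list(ccov = -sin(base$lag_ms / 30))),
                  class = "crosscov_result")
  expect_equal(average_crosscov(list(f1))$ccov, f1$ccov)
  expect_equal(max(abs(average_crosscov(list(f1, f2))$ccov)), 0)
  expect_error(average_crosscov(list()), "no eligible pairs")
})

test_that("peak lag breaks ties toward zero and flags flat functions", {
  lag_ms <- seq(-100, 100, by = 2)
  sym <- structure(list(lag_ms = lag_ms, ccov = -(lag_ms / 50)^2, band = "b",
                        pair_id = "p", n_windows_used = 1),
                   class = "crosscov_result")
  expect_equal(peak_lag(sym), 0)
  shifted <- sym; shifted$ccov <- -((lag_ms - 2) / 50)^2
  expect_equal(peak_lag(shifted), 2)
  neg <- sym; neg$ccov <- -((lag_ms + 30) / 50)^2
  expect_equal(peak_lag(neg), -30)
  flat <- sym; flat$ccov <- rep(1, length(lag_ms))
  pk <- peak_lag(flat)
  expect_equal(as.numeric(pk), 0)
  expect_true(attr(pk, "degenerate"))
  # exact tie at +10 and -10: zero-ward value wins, here the earlier index
  tie <- sym; tie$ccov <- abs(abs(lag_ms) - 10) * -1
  expect_equal(abs(peak_lag(tie)), 10)
})

test_that("the asymmetry index integrates signed area with a shared zero sample", {
  lag_ms <- seq(-200, 200, by = 2)
  even <- structure(list(lag_ms = lag_ms, ccov = cos(lag_ms / 40), band = "b",
                         pair_id = "p", n_windows_used = 1),
                    class = "crosscov_result")
  expect_equal(asymmetry_index(even), 0, tolerance = 1e-12)
  onesided <- even
  onesided$ccov <- ifelse(lag_ms > 0 & lag_ms <= 100, 1, 0)
  expect_gt(asymmetry_index(onesided), 0)
  short <- even
  short$lag_ms <- seq(-50, 50, by = 2)
  short$ccov <- numeric(51)
  expect_error(asymmetry_index(short), "lag grid")
  coh <- asymmetry_cohort(list(even, onesided))
  expect_equal(coh$n_positive, 1)
})

test_that("pair_crosscov recovers a pure envelope shift exactly", {
  x <- gen_background(60, 500, 1, -2, seed = 91)
  e1 <- band_envelope(x, 500, "theta")
  e2 <- c(rep(e1[1], 11), e1[1:(length(e1) - 11)])
  w2 <- window_2s(tibble::tibble(start_s = 0, end_s = 60))
  pc <- pair_crosscov(e1, e2, 500, w2, band = "theta")
  expect_equal(peak_lag(pc), 22)
  # exchanging the arguments flips the sign of the recovered lag
  pc_rev <- pair_crosscov(e2, e1, 500, w2, band = "theta")
  expect_equal(peak_lag(pc_rev), -22)
})

test_that("a theta-coupled cohort recovers its 22 ms envelope lag", {
  # theta envelopes are band-limited below 4 Hz, so the apex localises to
  # the envelope's intrinsic resolution (several ms), coarser than beta
  fs <- 500
  res <- lapply(seq_len(20), function(s) {
    pr <- gen_coherent_pair(240, fs, "theta", mixing_weight = 0.8,
                            bursts_per_min = 12, n_cycles = 3, snr = 10,
                            lag_ms = 22, seed = 12345 + 7 * s)
    env_d <- band_envelope(pr$a, fs, "theta")
    env_a <- band_envelope(pr$b, fs, "theta")
    w2 <- window_2s(tibble::tibble(start_s = 0, end_s = 240))
    use <- select_joint_top_quartile(
      window_envelope_power(env_d, fs, w2)$power,
      window_envelope_power(env_a, fs, w2)$power
    )
    pair_crosscov(env_d, env_a, fs, w2, use, band = "theta")
  })
  g <- average_crosscov(res)
  expect_lte(abs(peak_lag(g) - 22), 8)
  expect_gt(asymmetry_cohort(res)$fraction_positive, 0.8)
})
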
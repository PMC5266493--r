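four_channel_rec <- function(emg, eeg, eog_l, eog_r, rate = 500) {
  recording(
    rbind(emg, eeg, eog_l, eog_r), rate,
    tibble::tibble(
      label = c("EMG1", "C3", "EOGL", "EOGR"),
      modality = c("emg", "scalp_eeg", "eog_left", "eog_right")
    )
  )
}

test_that("opposite-polarity EOG deflections give a negative cross-covariance sum", {
  withr::with_seed(1, {
    n <- 30 * 500
    pulse <- sin(pi * seq(0, 1, length.out = 200))^2
    x <- numeric(n)
    for (s in seq(1000, n - 300, by = 3000)) x[s:(s + 199)] <- x[s:(s + 199)] + pulse
    noise <- rnorm(n, sd = 0.01)
  })
  rec <- four_channel_rec(noise, noise, x + noise, -x + noise)
  f <- epoch_features(rec)
  expect_lt(f$eog_xcov_sum, 0)
})

test_that("all-zero channels yield all-zero features", {
  z <- numeric(30 * 500)
  f <- epoch_features(four_channel_rec(z, z, z, z))
  expect_equal(unlist(f[, -1]), rep(0, 4), ignore_attr = TRUE)
})

test_that("missing modalities are named in the error", {
  rec <- recording(matrix(rnorm(2 * 15000), 2), 500,
                   tibble::tibble(label = c("a", "b"),
                                  modality = c("emg", "scalp_eeg")))
  expect_error(epoch_features(rec), "eog_left")
})

test_that("generated N3 epochs carry more delta power than REM epochs", {
  sess <- gen_session(small_scenario(seed = 2))
  f <- epoch_features(sess$recording)
  st <- sess$truth$hypnogram$stage
  expect_gt(min(f$delta_power[st == "N3"]), max(f$delta_power[st == "REM"]))
})

test_that("the REM rule labels exactly the qualifying epochs", {
  # hand-crafted features: epoch 5 is the only one below every quantile
  # threshold with a negative EOG sum
  n <- 25
  f <- tibble::tibble(
    epoch_index = 1:n,
    emg_power = c(rep(100, 4), 1, rep(100, n - 5)),
    delta_power = c(rep(50, 4), 2, rep(50, n - 5)),
    spindle_power = c(rep(40, 4), 1.5, rep(40, n - 5)),
    eog_xcov_sum = c(rep(1, 4), -3, rep(1, n - 5))
  )
  hyp <- classify_rem(f)
  expect_equal(which(hyp$stage == "REM"), 5)
  # flipping only the EOG sign removes the label
  f2 <- f; f2$eog_xcov_sum[5] <- 3
  expect_equal(sum(classify_rem(f2)$stage == "REM"), 0)
})

test_that("raising a quantile threshold never removes a REM label", {
  withr::with_seed(33, {
    f <- tibble::tibble(
      epoch_index = 1:60,
      emg_power = rexp(60), delta_power = rexp(60),
      spindle_power = rexp(60), eog_xcov_sum = rnorm(60)
    )
  })
  base <- classify_rem(f, 0.2, 0.3, 0.3)$stage == "REM"
  for (q in list(c(0.4, 0.3, 0.3), c(0.2, 0.6, 0.3), c(0.2, 0.3, 0.6),
                 c(0.5, 0.5, 0.5))) {
    wider <- classify_rem(f, q[1], q[2], q[3])$stage == "REM"
    expect_true(all(wider[base]))
  }
})

test_that("degenerate and undersized feature tables are handled", {
  f <- tibble::tibble(epoch_index = 1:25, emg_power = 1, delta_power = 1,
                      spindle_power = 1, eog_xcov_sum = 0)
  expect_warning(hyp <- classify_rem(f), "constant")
  expect_equal(sum(hyp$stage == "REM"), 0)
  expect_error(classify_rem(f[1:10, ]), "at least 20")
})

test_that("episode selection keeps strict >5 min uninterrupted REM runs", {
  # 11 consecutive REM epochs = 330 s: selected
  hyp <- hypnogram(c(rep("N2", 3), rep("REM", 11), rep("N2", 3)))
  eps <- select_rem_episodes(hyp)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$end_s - eps$start_s, 330, ignore_attr = TRUE)
  # 10 epochs = 300 s: rejected at the strict boundary
  hyp <- hypnogram(c(rep("N2", 3), rep("REM", 10), rep("N2", 3)))
  expect_equal(nrow(select_rem_episodes(hyp)), 0)
  # a single interrupting epoch splits the run into two short candidates
  hyp <- hypnogram(c(rep("REM", 8), "N2", rep("REM", 8)))
  expect_equal(nrow(select_rem_episodes(hyp)), 0)
  # both halves long enough -> two disjoint sorted episodes
  hyp <- hypnogram(c(rep("REM", 11), "N2", rep("REM", 12)))
  eps <- select_rem_episodes(hyp)
  expect_equal(nrow(eps), 2)
  expect_true(all(diff(eps$start_s) > 0))
  expect_true(all(eps$start_s[-1] >= eps$end_s[-nrow(eps)]))
  expect_true(all(eps$end_s - eps$start_s > 300))
})
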
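sine_epochs <- function(freq, amp = 1, fs = 150, n_trials = 1, nch = 2) {
  t_ms <- seq(-1000, 6000 - 1000 / fs, by = 1000 / fs)
  x <- amp * sin(2 * pi * freq * t_ms / 1000)
  dat <- array(rep(x, each = n_trials * nch), c(n_trials, nch, length(t_ms)))
  epoch_set(dat, fs)
}

test_that("the sliding spectrogram localizes pure tones on the 0.5-Hz grid", {
  tf <- stft_power(sine_epochs(10))
  expect_equal(length(tf$freqs), 59)
  expect_equal(tf$freqs[1], 1)
  expect_equal(tf$freqs[59], 30)
  peak_f <- tf$freqs[apply(tf$power[1, , ], 2, which.max)]
  expect_true(all(peak_f == 10))
  # window centres stay >= half a window from the epoch edges
  expect_gte(min(tf$times_ms), -1000 + 200)
  expect_lte(max(tf$times_ms), 6000 - 200)

  # zero input -> zero power
  z <- epoch_set(array(0, c(1, 2, 900)), 150)
  expect_true(all(stft_power(z)$power == 0))

  # quadratic amplitude scaling
  t1 <- stft_power(sine_epochs(10, amp = 1))
  t2 <- stft_power(sine_epochs(10, amp = 2))
  mid <- which.min(abs(t1$times_ms - 1000))
  expect_equal(t2$power[1, , mid] / t1$power[1, , mid], rep(4, 59),
               tolerance = 1e-8)

  expect_error(stft_power(epoch_set(array(0, c(1, 1, 30)), 150)),
               "longer than")
})

test_that("summed white-noise power grows linearly with window count", {
  set.seed(1)
  fs <- 150
  long <- epoch_set(array(rnorm(10 * 4 * 7 * fs), c(10, 4, 7 * fs)), fs)
  tf <- stft_power(long)
  nwin <- length(tf$times_ms)
  cum <- cumsum(apply(tf$power, 3, sum))
  # total power after k windows ~ k * mean-per-window (5% tolerance at the end)
  lin <- seq_along(cum) * cum[length(cum)] / length(cum)
  expect_lt(max(abs(cum - lin) / cum[length(cum)]), 0.05)
})

test_that("baseline normalization gives relative change and scale invariance", {
  set.seed(2)
  fs <- 150
  dat <- array(rnorm(6 * 3 * 7 * fs), c(6, 3, 7 * fs))
  tf <- stft_power(epoch_set(dat, fs))
  nm <- baseline_normalize_tfr(tf)
  # stationary signal: ~0 everywhere after normalization
  expect_lt(median(abs(nm$power)), 0.5)
  expect_lt(abs(mean(nm$power)), 0.12)

  # power doubling after onset: value ~ 1 post-onset
  dat2 <- dat
  t_ms <- seq(-1000, by = 1000 / fs, length.out = 7 * fs)
  post <- t_ms >= 0
  dat2[, , post] <- dat2[, , post] * sqrt(2)
  nm2 <- baseline_normalize_tfr(stft_power(epoch_set(dat2, fs)))
  late <- nm2$times_ms > 500 & nm2$times_ms < 4000
  expect_equal(mean(nm2$power[, , late]), 1, tolerance = 0.15)

  # global rescaling leaves the normalized TFR unchanged
  nm3 <- baseline_normalize_tfr(stft_power(epoch_set(dat * 13, fs)))
  expect_equal(nm3$power, nm$power, tolerance = 1e-10)

  expect_error(baseline_normalize_tfr(tf, c(-5000, -4500)), "baseline")
})

test_that("band averaging uses inclusive edges on the 0.5-Hz grid", {
  tf <- stft_power(sine_epochs(10))
  # alpha 8-13 inclusive: 11 bins
  expect_equal(sum(tf$freqs >= 8 & tf$freqs <= 13), 11)
  bp <- band_power(tf, c(8, 13))
  expect_equal(dim(bp), c(2, length(tf$times_ms)))
  # single-bin band returns that bin
  b1 <- band_power(tf, c(10, 10))
  expect_equal(b1[1, ], tf$power[1, which(tf$freqs == 10), ])
  # flat spectrum: all bands agree
  flat <- tf; flat$power[] <- 3
  expect_equal(band_power(flat, c(1, 4)), band_power(flat, c(14, 20)))
  expect_error(band_power(tf, c(31, 35)), "empty")
})

test_that("band x stage cluster tests find planted effects in band and stage", {
  arr <- tiny_array(24)
  fs <- 120
  np <- 8
  topo <- make_topography(arr, c(-pi / 2, 0.4), 0.6)
  set.seed(3)
  quiet <- noise_params(one_over_f_scale = 1, line_scale = 0,
                        drift_scale = 0, sensor_scale = 0.3)
  mk <- function(amp) {
    eff <- list(effect_spec("band_power", c(2500, 3650), amp, amp, topo,
                            band = c(8.5, 12.5), base = 1))
    params <- sim_params(fs_hz = fs, noise = quiet, effects = eff, seed = 1)
    lapply(1:np, function(p) {
      dat <- array(0, c(10, 24, 7 * fs))
      for (i in 1:10)
        dat[i, , ] <- simulate_trial_signal("correct", params, arr)
      baseline_normalize_tfr(stft_power(epoch_set(dat, fs)))
    })
  }
  tf_hi <- mk(2.2)
  tf_lo <- mk(1.0)
  r <- tfr_stage_cluster_test(tf_hi, tf_lo, c(8, 13), "maintenance", arr,
                              n_perm = 200, seed = 4)
  expect_gt(length(r$clusters), 0)
  best <- r$clusters[[1]]
  expect_lt(best$p, 0.05)
  expect_equal(best$sign, 1)
  span <- cluster_time_span(best, r)
  overlap <- min(span[2], 3650) - max(span[1], 2500)
  expect_gte(overlap / (span[2] - span[1]), 0.5)

  # the same data show no delta-band cluster (band specificity)
  rd <- tfr_stage_cluster_test(tf_hi, tf_lo, c(1, 4), "maintenance", arr,
                               n_perm = 200, seed = 5)
  expect_gte(min_cluster_p(rd), 0.05)

  # identical conditions: empty
  r0 <- tfr_stage_cluster_test(tf_hi, tf_hi, c(8, 13), "maintenance", arr,
                               n_perm = 100, seed = 6)
  expect_length(r0$clusters, 0)
})
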
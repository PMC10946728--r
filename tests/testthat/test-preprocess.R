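make_epochs <- function(dat, fs = 100) epoch_set(dat, fs)

test_that("trial-power outlier rejection follows the 2-SD rule", {
  set.seed(1)
  base <- array(rnorm(10 * 4 * 700), c(10, 4, 700))
  # identical trials: zero SD -> nothing rejected
  same <- array(rep(base[1, , ], each = 10), c(10, 4, 700))
  r <- reject_outlier_trials(make_epochs(same))
  expect_length(r$rejected, 0)

  # one trial scaled x10 is the only one rejected
  scaled <- base
  scaled[7, , ] <- scaled[7, , ] * 10
  r2 <- reject_outlier_trials(make_epochs(scaled))
  expect_equal(r2$rejected, 7)
  expect_equal(n_trials(r2$epochs), 9)

  # infinite threshold is the identity
  r3 <- reject_outlier_trials(make_epochs(base), z_thresh = Inf)
  expect_length(r3$rejected, 0)
  expect_identical(r3$epochs$data, base)

  expect_error(reject_outlier_trials(make_epochs(base[1:2, , , drop = FALSE])),
               "3 trials")
})

test_that("DSS scores and components behave on constructed data", {
  # a single repeated deterministic trial: bias == total covariance
  fs <- 150
  t_ms <- seq(-1000, 6000 - 1000 / fs, by = 1000 / fs)
  src <- sin(2 * pi * 5 * t_ms / 1000)
  mix <- matrix(rnorm(8 * 2), 8, 2)
  trial <- mix %*% rbind(src, cos(2 * pi * 9 * t_ms / 1000))
  dat <- array(rep(trial, each = 6), c(6, 8, length(t_ms)))
  dat <- aperm(array(trial, c(8, length(t_ms), 6)), c(3, 1, 2))
  m <- dss_decompose(make_epochs(dat, fs))
  expect_equal(m$scores[1], 1, tolerance = 1e-8)
  expect_equal(m$scores[2], 1, tolerance = 1e-8)

  # planted phase-locked source under strong non-phase-locked noise
  fx <- planted_source_epochs()
  model <- dss_decompose(fx$epochs)
  avg <- erf_average(fx$epochs)
  comp1 <- as.numeric(crossprod(model$filters[, 1, drop = FALSE], avg))
  expect_gt(abs(stats::cor(comp1, fx$source)), 0.9)

  # pure-noise bias window: scores at the ~1/n_trials level
  set.seed(3)
  noise <- array(rnorm(50 * 10 * 1050), c(50, 10, 1050))
  mn <- dss_decompose(make_epochs(noise, 150))
  expect_lt(mn$scores[1], 5 / 50)

  # scale equivariance of scores
  sc <- dss_decompose(make_epochs(noise * 37.5, 150))
  expect_equal(sc$scores, mn$scores, tolerance = 1e-8)
})

test_that("DSS denoising projects and round-trips correctly", {
  fx <- planted_source_epochs(n_trials = 20, nch = 12)
  model <- dss_decompose(fx$epochs)
  den_all <- dss_denoise(fx$epochs, model, model$rank)
  expect_equal(den_all$data, fx$epochs$data, tolerance = 1e-8)

  den2 <- dss_denoise(fx$epochs, model, 2)
  expect_identical(dim(den2$data), dim(fx$epochs$data))
  # rank-2 spatial structure
  flat <- matrix(den2$data, dim(den2$data)[1] * 1, )
  x <- den2$data[1, , ]
  expect_lt(qr(x)$rank, 3)
  expect_error(dss_denoise(fx$epochs, model, 0), "keep")
  expect_error(dss_denoise(fx$epochs, model, model$rank + 1), "keep")

  # keep = 1 removes the weaker-bias of two orthogonal planted sources
  fs <- 150
  t_ms <- seq(-1000, 6000 - 1000 / fs, by = 1000 / fs)
  s_strong <- sin(2 * pi * 4 * t_ms / 1000)
  n <- length(t_ms)
  topo_a <- c(1, rep(0, 7)); topo_b <- c(rep(0, 7), 1)
  set.seed(9)
  dat <- array(0, c(24, 8, n))
  for (i in 1:24) {
    s_weak <- rnorm(n)  # non-reproducible across trials
    dat[i, , ] <- tcrossprod(topo_a, s_strong) + tcrossprod(topo_b, s_weak)
  }
  ep <- make_epochs(dat, fs)
  m2 <- dss_decompose(ep)
  d1 <- dss_denoise(ep, m2, 1)
  # the reproducible source's channel keeps its variance, the noise channel's
  # content is almost entirely removed
  expect_gt(stats::sd(d1$data[1, 1, ]) / stats::sd(dat[1, 1, ]), 0.9)
  expect_lt(stats::sd(d1$data[1, 8, ]) / stats::sd(dat[1, 8, ]), 0.2)
})

test_that("baseline correction subtracts the prestimulus mean", {
  fs <- 100
  n <- 700
  const <- array(5, c(3, 2, n))
  b <- baseline_correct(make_epochs(const, fs))
  expect_true(all(b$data == 0))

  # idempotence on already-corrected data
  set.seed(2)
  dat <- array(rnorm(3 * 2 * n), c(3, 2, n))
  b1 <- baseline_correct(make_epochs(dat, fs))
  b2 <- baseline_correct(b1)
  expect_equal(b1$data, b2$data, tolerance = 1e-12)

  # linear ramp in time: value at t = -250 ms ~ 0 after correction
  t_ms <- seq(-1000, 6000 - 1000 / fs, by = 1000 / fs)
  ramp <- array(rep(t_ms, each = 3 * 2), c(3, 2, n))
  br <- baseline_correct(make_epochs(ramp, fs))
  i250 <- which.min(abs(t_ms + 250))
  expect_lt(abs(br$data[1, 1, i250]), 1000 / fs)
  expect_error(baseline_correct(make_epochs(dat, fs), c(-5000, -4000)),
               "outside")
})

test_that("trial-count equating keeps the fastest correct trials", {
  dat <- array(seq_len(3 * 2 * 10), c(3, 2, 10))
  cor_ep <- make_epochs(dat)
  # RTs 900, 1200, 800 with 2 incorrect trials -> keep RTs 800 and 900
  eq <- equate_trial_counts(cor_ep, rt_ms = c(900, 1200, 800), n_incorrect = 2)
  expect_equal(eq$trial_ids, c(1, 3))

  # no surplus: all retained
  eq2 <- equate_trial_counts(cor_ep, rt_ms = c(1, 2, 3), n_incorrect = 3)
  expect_equal(n_trials(eq2), 3)

  # ties broken by trial index
  eq3 <- equate_trial_counts(cor_ep, rt_ms = c(5, 5, 5), n_incorrect = 2)
  expect_equal(eq3$trial_ids, c(1, 2))

  expect_error(equate_trial_counts(cor_ep, rt_ms = c(1, 2, 3),
                                   n_incorrect = 4), "fewer correct")
})

test_that("the participant pipeline equates conditions end to end", {
  sim <- mini_participant()
  prep <- suppressWarnings(preprocess_participant(sim$epochs, sim$behavior))
  expect_equal(n_trials(prep$correct), n_trials(prep$incorrect))
  expect_equal(prep$report$n_equated, prep$report$n_incorrect)
  expect_true(all(diff(prep$dss$scores) <= 1e-12))
  expect_length(prep$rt_correct, n_trials(prep$correct))
  # retained correct trials are the fastest ones
  beh <- prep$behavior
  rt_cor <- beh$rt_ms[beh$condition == "correct"]
  expect_lte(max(prep$rt_correct), sort(rt_cor)[n_trials(prep$correct)])
})
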
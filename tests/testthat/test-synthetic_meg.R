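test_that("sensor arrays have helmet-like geometry and a usable graph", {
  arr <- make_sensor_array(274, seed = 1)
  expect_equal(arr$n_channels, 274)
  expect_equal(dim(arr$positions), c(274, 3))
  # unit vectors on the upper hemisphere
  expect_equal(rowSums(arr$positions^2), rep(1, 274), tolerance = 1e-12)
  expect_true(all(arr$positions[, 3] >= 0))
  deg <- lengths(arr$adjacency)
  expect_true(stats::median(deg) >= 6 && stats::median(deg) <= 8)
  expect_true(all(deg >= 2))
  # no self-edges; symmetric
  for (j in c(1, 50, 274)) {
    expect_false(j %in% arr$adjacency[[j]])
    for (k in arr$adjacency[[j]]) expect_true(j %in% arr$adjacency[[k]])
  }
  expect_identical(make_sensor_array(64, seed = 9)$positions,
                   make_sensor_array(64, seed = 9)$positions)
  expect_error(make_sensor_array(4), "at least 8")

  # small arrays stay connected
  a8 <- make_sensor_array(8, seed = 1)
  reach <- c(1); repeat {
    nxt <- unique(c(reach, unlist(a8$adjacency[reach])))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_length(reach, 8)
})

test_that("topographies behave in flat, Gaussian and dipolar modes", {
  arr <- tiny_array(64)
  flat <- make_topography(arr, c(0, pi / 4), Inf)
  expect_equal(flat, rep(1, 64))

  w <- make_topography(arr, c(pi, 0.4), 0.5)
  expect_equal(max(abs(w)), 1)
  expect_true(all(w > 0))

  d <- make_topography(arr, c(0, pi / 4), 0.3, dipolar = TRUE,
                       lobe_sep = pi / 2)
  # two lobes of opposite polarity; near-zero total weight
  expect_lt(abs(sum(d)) / sum(abs(d)), 0.05)
  ctr <- astmeg:::direction_vector(0, pi / 4)
  c1 <- astmeg:::rotate_about(ctr, c(0, 0, 1), pi / 4)
  c2 <- astmeg:::rotate_about(ctr, c(0, 0, 1), -pi / 4)
  w1 <- d[which.max(arr$positions %*% c1)]
  w2 <- d[which.max(arr$positions %*% c2)]
  expect_true(sign(w1) != sign(w2))
  expect_error(make_topography(arr, c(0, 0), -1), "positive")
})

test_that("trial signals are exact sums of planted components", {
  arr <- tiny_array(32)
  quiet <- noise_params(one_over_f_scale = 0, line_scale = 0,
                        drift_scale = 0, sensor_scale = 0)
  # no effects, no noise -> zero epoch
  p0 <- sim_params(fs_hz = 120, noise = quiet, effects = list(), seed = 1)
  expect_true(all(simulate_trial_signal("correct", p0, arr) == 0))

  # single sustained effect, no noise, no trial jitter -> exact outer product
  topo <- make_topography(arr, c(pi, 0.4), 0.5)
  eff <- list(effect_spec("erf_sustained", c(0, 4500), 2, 1, topo))
  p1 <- sim_params(fs_hz = 120, noise = quiet, effects = eff, trial_sd = 0,
                   seed = 1)
  ep <- simulate_trial_signal("correct", p1, arr)
  t_ms <- seq(-1000, 6000 - 1000 / 120, by = 1000 / 120)
  expect_equal(ep, tcrossprod(topo, 2 * smooth_boxcar(t_ms, 0, 4500, 250)))
  ei <- simulate_trial_signal("incorrect", p1, arr)
  expect_equal(ei, ep / 2)

  # steady-state at 3 Hz, no noise -> encoding spectrum peaks at 3 Hz
  eff3 <- list(effect_spec("steady_state", c(0, 2500), 1, 1, topo,
                           rate_hz = 3))
  p3 <- sim_params(fs_hz = 120, noise = quiet, effects = eff3, trial_sd = 0,
                   seed = 1)
  e3 <- simulate_trial_signal("correct", p3, arr)
  ch <- which.max(abs(topo))
  enc <- which(t_ms >= 0 & t_ms < 2500)
  spec <- Mod(stats::fft(e3[ch, enc]))^2
  fr <- (seq_along(spec) - 1) / length(spec) * 120
  half <- fr <= 60 & fr >= 0.5
  # all energy lies on the 3-Hz harmonic comb...
  pk <- fr[half][which.max(spec[half])]
  expect_lt(min(abs(pk - 3 * (1:20))), 0.45)
  # ...with strong energy in the fundamental band and none off-harmonic
  bandE <- function(lo, hi) sum(spec[fr >= lo & fr <= hi])
  expect_gt(bandE(2.5, 3.5), 20 * bandE(4.2, 5.2))

  # window outside the epoch errors
  bad <- list(effect_spec("erf_sustained", c(0, 7000), 1, 1, topo))
  pb <- sim_params(fs_hz = 120, noise = quiet, effects = bad, seed = 1)
  expect_error(simulate_trial_signal("correct", pb, arr), "outside")
})

test_that("behavioural simulation follows the response policy", {
  # degenerate policies
  all_same <- behavior_params(p_hit = c(`3` = 1, `7` = 1, `19` = 1),
                              p_fa = c(`3` = 1, `7` = 1, `19` = 1),
                              bias_3hz = 0)
  set.seed(1)
  expect_equal(simulate_behavior("same", 7, all_same)$outcome, "TP")
  expect_equal(simulate_behavior("different", 7, all_same)$outcome, "FP")

  expect_equal(classify_outcome(c("same", "same", "different", "different"),
                                c("same", "different", "same", "different")),
               c("TP", "FN", "FP", "TN"))

  # unbiased coin: TP fraction ~ 0.25 of all trials under a 50/50 class mix
  fair <- behavior_params(p_hit = c(`3` = 0.5, `7` = 0.5, `19` = 0.5),
                          p_fa = c(`3` = 0.5, `7` = 0.5, `19` = 0.5),
                          bias_3hz = 0)
  set.seed(2)
  n <- 20000
  cls <- rep(c("same", "different"), n / 2)
  out <- vapply(cls, function(cl)
    simulate_behavior(cl, 7, fair)$outcome, "")
  frac_tp <- mean(out == "TP")
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(frac_tp - 0.25), 4 * se)

  bad <- behavior_params()
  bad$p_hit[["3"]] <- 1.2
  expect_error(simulate_behavior("same", 3, bad), "outside")
})

test_that("participant simulation ties epochs to behavioural outcomes", {
  sim <- mini_participant()
  expect_equal(n_trials(sim$epochs), 30)
  expect_equal(nrow(sim$behavior), 30)
  expect_true(all(sim$behavior$outcome %in% c("TP", "TN", "FP", "FN")))
  expect_true(all(sim$behavior$rt_ms > 0))
})

test_that("phase-locked components survive averaging; induced ones do not", {
  arr <- tiny_array(32)
  topo <- make_topography(arr, c(pi, 0.4), 0.5)
  quiet <- noise_params(one_over_f_scale = 0, line_scale = 0,
                        drift_scale = 0, sensor_scale = 0)
  eff <- list(
    effect_spec("steady_state", c(0, 2500), 1, 1, topo, rate_hz = 3,
                label = "ss"),
    effect_spec("band_power", c(0, 2500), 1, 1, topo, band = c(8, 13),
                base = 1, label = "bp")
  )
  pars <- sim_params(fs_hz = 120, noise = quiet, effects = eff, trial_sd = 0,
                     seed = 1)
  set.seed(7)
  n <- 30
  acc <- 0
  singles <- numeric(n)
  course <- steady_state_course(3, seq(-1000, 6000 - 1000 / 120, by = 1000 / 120), 120)
  ch <- which.max(abs(topo))
  for (i in seq_len(n)) {
    ep <- simulate_trial_signal("correct", pars, arr)
    acc <- acc + ep
    singles[i] <- stats::sd(ep[ch, ]) # total single-trial amplitude
  }
  avg <- acc / n
  # the phase-locked part keeps its full amplitude under averaging: the
  # regression of the average onto the course recovers the planted gain
  gain <- sum(avg[ch, ] * course) / sum(course^2)
  expect_equal(gain, topo[ch], tolerance = 0.05)
  # ...while the induced band noise attenuates roughly as 1/sqrt(n)
  resid <- avg[ch, ] - topo[ch] * course
  expect_lt(stats::sd(resid), mean(singles) / sqrt(n) * 3)
})

test_that("studies are written incrementally and reproducibly", {
  arr <- tiny_array(16)
  pars <- sim_params(fs_hz = 120, effects = default_effects(arr), seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_study(3, arr, pars, n_per_cell = 1, seed = 6, outdir = d1)
  m2 <- simulate_study(3, arr, pars, n_per_cell = 1, seed = 6, outdir = d2)
  expect_equal(nrow(m1), 3)
  expect_true(all(file.exists(m1$epochs)))
  e1 <- read_epochs(m1$epochs[2])
  e2 <- read_epochs(m2$epochs[2])
  expect_identical(e1$data, e2$data)
  b1 <- read.csv(m1$behavior[1]); b2 <- read.csv(m2$behavior[1])
  expect_identical(b1, b2)
  expect_error(simulate_study(1, arr, pars), ">= 2")
})
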
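# Synthetic MEG study generator.
#
# Produces per-trial multi-channel epochs as a sum of planted components and
# structured noise:
#   * erf_sustained  - a smoothed-boxcar evoked field, larger on correct trials;
#   * steady_state   - stimulus-locked response at each stream rate, identical
#                      across trials of a rate (phase-locked), with amplitude
#                      ordering 3 > 7 > 19 Hz and no condition difference by
#                      default;
#   * band_power     - non-phase-locked band-limited activity whose envelope is
#                      elevated inside a time window, more so on correct trials;
# noise = spatially correlated 1/f background (latent sources mixed through
# smooth random topographies), a 50-Hz line component with random phase per
# trial, integrated-random-walk drift, and a white sensor floor.
#
# Behavioural responses are drawn from per-rate "respond same" probabilities
# with a 3-Hz bias increment; response times are log-normal with
# outcome-dependent location (TP < TN < FN < FP).

#' Planted effect specification
#'
#' @param kind One of `"erf_sustained"`, `"steady_state"`, `"band_power"`.
#' @param window_ms `c(start, end)` in ms relative to scene onset.
#' @param amp_correct,amp_incorrect Amplitudes (arbitrary units, >= 0) on
#'   correct / incorrect trials.
#' @param band `c(f_lo, f_hi)` Hz for `band_power`.
#' @param rate_hz Stream rate (3, 7 or 19) for `steady_state`.
#' @param topography Channel weight vector (from [make_topography()]).
#' @param base Baseline envelope level outside the window (band_power only).
#' @param label Optional name used in reports.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(kind, window_ms, amp_correct, amp_incorrect,
                        topography, band = NULL, rate_hz = NULL,
                        base = 1, label = kind) {
  kind <- match.arg(kind, c("erf_sustained", "steady_state", "band_power"))
  if (amp_correct < 0 || amp_incorrect < 0) stop("amplitudes must be >= 0")
  if (kind == "band_power" && is.null(band)) stop("band_power needs `band`")
  if (kind == "steady_state" && is.null(rate_hz)) stop("steady_state needs `rate_hz`")
  structure(list(kind = kind, window_ms = window_ms,
                 amp_correct = amp_correct, amp_incorrect = amp_incorrect,
                 topography = topography, band = band, rate_hz = rate_hz,
                 base = base, label = label),
            class = "effect_spec")
}

#' Default noise parameters
#'
#' @param one_over_f_exp Spectral exponent of the background (power ~ 1/f^a).
#' @param one_over_f_scale SD of the mixed background at the sensors.
#' @param n_latent Number of latent background sources.
#' @param line_hz,line_scale Line-noise frequency and sensor-level SD.
#' @param drift_scale SD of the integrated-random-walk drift.
#' @param sensor_scale SD of the white sensor noise floor.
#' @export
noise_params <- function(one_over_f_exp = 1, one_over_f_scale = 1,
                         n_latent = 20, line_hz = 50, line_scale = 0.3,
                         drift_scale = 0.5, sensor_scale = 0.2) {
  list(one_over_f_exp = one_over_f_exp, one_over_f_scale = one_over_f_scale,
       n_latent = n_latent, line_hz = line_hz, line_scale = line_scale,
       drift_scale = drift_scale, sensor_scale = sensor_scale)
}

#' Default behavioural parameters
#'
#' Per-rate probabilities of responding "same", a 3-Hz bias increment applied
#' in both trial classes, and log-normal RT parameters ordered
#' TP < TN < FN < FP, with responses to 3-Hz probes slightly faster when
#' "same" is given and slightly slower for true negatives. Defaults target
#' an overall accuracy near 71%.
#'
#' @param p_hit Named per-rate P(respond same | same trial), before bias.
#' @param p_fa Named per-rate P(respond same | different trial), before bias.
#' @param bias_3hz Additive increment to P(respond same) for 3-Hz probes.
#' @param rt_meanlog Named log-RT locations (ms) per outcome.
#' @param rt_sdlog Log-RT scale.
#' @param rt_rate_mod Named multiplicative log-RT shifts for 3-Hz probes by
#'   outcome.
#' @export
behavior_params <- function(p_hit = c(`3` = 0.72, `7` = 0.66, `19` = 0.62),
                            p_fa = c(`3` = 0.32, `7` = 0.22, `19` = 0.20),
                            bias_3hz = 0.13,
                            rt_meanlog = c(TP = log(870), TN = log(1000),
                                           FN = log(1090), FP = log(1140)),
                            rt_sdlog = 0.25,
                            rt_rate_mod = c(TP = -0.08, FP = -0.08,
                                            TN = 0.05, FN = 0)) {
  p <- c(p_hit + c(bias_3hz, 0, 0), p_fa + c(bias_3hz, 0, 0))
  if (any(p < 0 | p > 1)) stop("response probabilities must lie in [0, 1]")
  list(p_hit = p_hit, p_fa = p_fa, bias_3hz = bias_3hz,
       rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog, rt_rate_mod = rt_rate_mod)
}

#' Simulation parameter container
#'
#' @param fs_hz Sampling rate (study value 600).
#' @param epoch_ms `c(t0, t_end)` epoch limits in ms (study: -1000 to 6000).
#' @param noise A [noise_params()] list.
#' @param effects List of [effect_spec()] objects.
#' @param behavior A [behavior_params()] list.
#' @param participant_sd SD (log scale) of per-participant random scaling of
#'   effect amplitudes.
#' @param trial_sd SD (log scale) of per-trial random scaling of the
#'   phase-locked (ERF and steady-state) components: evoked amplitude varies
#'   from trial to trial, so concatenated-trial spectra carry energy at the
#'   stimulation frequencies themselves rather than only on the trial-period
#'   comb.
#' @param ss_model Steady-state response model: `"onset_kernel"` (per-tone
#'   evoked kernel convolved with the onset train; produces harmonics) or
#'   `"envelope_bandpass"` (stimulus envelope band-passed around the rate).
#' @param seed Master seed.
#' @export
sim_params <- function(fs_hz = 600, epoch_ms = c(-1000, 6000),
                       noise = noise_params(), effects = list(),
                       behavior = behavior_params(),
                       participant_sd = 0.15, trial_sd = 0.2,
                       ss_model = c("onset_kernel", "envelope_bandpass"),
                       seed = 1L) {
  ss_model <- match.arg(ss_model)
  if (fs_hz <= 2 * noise$line_hz)
    stop("fs_hz must exceed twice the line frequency")
  list(fs_hz = fs_hz, epoch_ms = epoch_ms, noise = noise, effects = effects,
       behavior = behavior, participant_sd = participant_sd,
       trial_sd = trial_sd, ss_model = ss_model, seed = seed)
}

#' Default planted effects
#'
#' The shipped effect set mirrors the qualitative structure of the study's
#' findings: a sustained evoked field across encoding and maintenance (larger
#' on correct trials), steady-state responses at 3/7/19 Hz during encoding
#' (amplitude 3 > 7 > 19, equal across conditions), and band-limited power
#' increases for correct trials in the theta (1560-2410 ms), alpha (1500-2500
#' and 2500-3650 ms) and beta (646-1281, 2632-3340 and 3766-4510 ms) windows.
#'
#' The planted oscillations occupy the physiological core of each band
#' (theta 4.5-6.5, alpha 8.5-12.5, beta 14.5-19.5 Hz) rather than the full
#' analysis band, keeping taper-smoothing leakage across band boundaries
#' small.
#'
#' @param array A `sensor_array`.
#' @param erf_amp,ss_amp,band_amp Overall amplitude scales for the three
#'   effect families (`band_amp` = c(correct, incorrect) envelope SDs).
#' @return List of `effect_spec` objects.
#' @export
default_effects <- function(array, erf_amp = c(correct = 2.2, incorrect = 1.5),
                            ss_amp = c(`3` = 2.4, `7` = 1.6, `19` = 1.1),
                            band_amp = c(correct = 2.1, incorrect = 1.2)) {
  topo <- list(
    erf   = make_topography(array, direction_vector(pi, 0.45), 0.55, dipolar = TRUE,
                            lobe_sep = 0.9),
    ss    = make_topography(array, direction_vector(pi * 0.9, 0.5), 0.6, dipolar = TRUE,
                            lobe_sep = 0.8),
    theta = make_topography(array, direction_vector(pi, 0.35), 0.5),
    alpha = make_topography(array, direction_vector(-pi / 2, 0.4), 0.6),
    beta  = make_topography(array, direction_vector(pi * 0.75, 0.55), 0.5)
  )
  eff <- list(
    # the sustained field persists through the probe stage (stimulus and
    # response activity follow maintenance), so no repeating offset ramp
    # falls inside the analysed stages
    effect_spec("erf_sustained", c(0, 6000), erf_amp[["correct"]],
                erf_amp[["incorrect"]], topo$erf, label = "erf_sustained"),
    effect_spec("steady_state", c(0, 2500), ss_amp[["3"]], ss_amp[["3"]],
                topo$ss, rate_hz = 3, label = "ss_3hz"),
    effect_spec("steady_state", c(0, 2500), ss_amp[["7"]], ss_amp[["7"]],
                topo$ss, rate_hz = 7, label = "ss_7hz"),
    effect_spec("steady_state", c(0, 2500), ss_amp[["19"]], ss_amp[["19"]],
                topo$ss, rate_hz = 19, label = "ss_19hz"),
    effect_spec("band_power", c(1560, 2410), band_amp[["correct"]],
                band_amp[["incorrect"]], topo$theta, band = c(4.5, 6.5),
                label = "theta_encoding"),
    effect_spec("band_power", c(1500, 2500), band_amp[["correct"]],
                band_amp[["incorrect"]], topo$alpha, band = c(8.5, 12.5),
                label = "alpha_encoding"),
    effect_spec("band_power", c(2500, 3650), band_amp[["correct"]],
                band_amp[["incorrect"]], topo$alpha, band = c(8.5, 12.5),
                label = "alpha_maintenance"),
    effect_spec("band_power", c(646, 1281), band_amp[["correct"]],
                band_amp[["incorrect"]], topo$beta, band = c(14.5, 19.5),
                label = "beta_encoding"),
    effect_spec("band_power", c(2632, 3340), band_amp[["correct"]],
                band_amp[["incorrect"]], topo$beta, band = c(14.5, 19.5),
                label = "beta_maintenance_1"),
    effect_spec("band_power", c(3766, 4510), band_amp[["correct"]],
                band_amp[["incorrect"]], topo$beta, band = c(14.5, 19.5),
                label = "beta_maintenance_2")
  )
  names(eff) <- vapply(eff, `[[`, "", "label")
  eff
}

#' Equalize condition amplitudes of an effect list
#'
#' Sets every effect's incorrect-trial amplitude equal to its correct-trial
#' amplitude, yielding a null generator for type-I-error studies.
#'
#' @param effects List of `effect_spec` objects.
#' @export
null_effects <- function(effects) {
  lapply(effects, function(e) { e$amp_incorrect <- e$amp_correct; e })
}

# ---------------------------------------------------------------------------
# Signal building blocks

# 1/f^(a/2) amplitude-shaped noise columns: returns n x k matrix, unit SD.
colored_noise <- function(n, k, exponent) {
  w <- matrix(stats::rnorm(n * k), n, k)
  if (exponent == 0) return(w)
  W <- stats::mvfft(w)
  f <- c(1e-12, seq_len(n - 1))           # cycles per series; DC suppressed
  f <- pmin(f, n - f)                     # two-sided frequency index
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::mvfft(W * shape, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

# Band-limited Gaussian noise columns (FFT brick-wall), unit SD.
bandlimited_noise <- function(n, k, fs, f_lo, f_hi) {
  w <- matrix(stats::rnorm(n * k), n, k)
  W <- stats::mvfft(w)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  keep <- f >= f_lo & f <= f_hi
  W[!keep, ] <- 0
  x <- Re(stats::mvfft(W, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

# Per-tone evoked response kernel: a slow monophasic lobe (~120 ms, giving a
# dominant fundamental at slow rates) plus a faster biphasic deflection
# (~70 ms, keeping energy near 14-20 Hz so fast rates register too).
onset_kernel <- function(fs) {
  n1 <- max(4L, round(0.12 * fs))
  slow <- hann_window(n1)
  n2 <- max(4L, round(0.07 * fs))
  fast <- sin(2 * pi * seq_len(n2) / n2) * hann_window(n2)
  n <- max(n1, n2)
  k <- numeric(n)
  k[seq_len(n1)] <- k[seq_len(n1)] + slow
  k[seq_len(n2)] <- k[seq_len(n2)] + 0.6 * fast
  k
}

# Deterministic steady-state time course for one stream rate: onset impulse
# train convolved with the per-tone kernel (or band-passed stimulus
# envelope), placed in [0, 2500) ms; unit peak scale. Phase-locked: identical
# on every trial.
steady_state_course <- function(rate_hz, t_ms, fs, model = "onset_kernel") {
  n <- length(t_ms)
  enc <- t_ms >= 0 & t_ms < 2500
  x <- numeric(n)
  if (model == "onset_kernel") {
    tm <- stream_timing(rate_hz)
    onsets <- seq(0, 2500, by = tm$soa_ms)
    onsets <- onsets[onsets + tm$tone_dur_ms <= 2500]
    imp <- numeric(n)
    idx <- round((onsets - t_ms[1]) / 1000 * fs) + 1L
    imp[idx[idx >= 1 & idx <= n]] <- 1
    ker <- onset_kernel(fs)
    full <- stats::filter(imp, ker, method = "convolution", sides = 1)
    full[is.na(full)] <- 0
    x <- as.numeric(full)   # kernel tails decay naturally past scene offset
  } else {
    env <- synth_pip_train(rate_hz, 2500, fs)
    env <- env - mean(env)
    m <- length(env)
    E <- stats::fft(env)
    f <- (seq_len(m) - 1) / m * fs
    f <- pmin(f, fs - f)
    keep <- f >= rate_hz - 1 & f <= rate_hz + 1
    E[!keep] <- 0
    bp <- Re(stats::fft(E, inverse = TRUE)) / m
    x[which(enc)[seq_len(min(m, sum(enc)))]] <- bp[seq_len(min(m, sum(enc)))]
  }
  # confine the response to the scene: smooth gate to zero by scene offset,
  # so no phase-locked content repeats inside the maintenance stage
  x <- x * smooth_boxcar(t_ms, 0, 2500, 100)
  if (max(abs(x)) > 0) x <- x / max(abs(x))
  x
}

# Per-participant noise spatial structure: latent mixing matrices.
make_noise_mixing <- function(array, noise) {
  nch <- array$n_channels
  rand_topo <- function() {
    ctr <- direction_vector(stats::runif(1, 0, 2 * pi),
                            stats::runif(1, 0.1, pi / 2))
    make_topography(array, ctr, stats::runif(1, 0.3, 0.9)) *
      stats::rnorm(1, 1, 0.3)
  }
  list(
    background = vapply(seq_len(noise$n_latent), function(i) rand_topo(),
                        numeric(nch)),
    line  = rand_topo(),
    drift = vapply(1:3, function(i) rand_topo(), numeric(nch))
  )
}

#' Simulate a single-trial epoch
#'
#' @param condition `"correct"` or `"incorrect"`.
#' @param params A [sim_params()] list.
#' @param array A `sensor_array`.
#' @param mixing Noise mixing structure (internal; built once per participant
#'   by [simulate_participant()]; defaults to a fresh one).
#' @param amp_scale Per-participant multiplicative scaling of effect
#'   amplitudes (named by effect label, default all 1).
#' @return channels x time numeric matrix.
#' @export
simulate_trial_signal <- function(condition, params, array,
                                  mixing = NULL, amp_scale = NULL) {
  fs <- params$fs_hz
  t_ms <- seq(params$epoch_ms[1], params$epoch_ms[2] - 1000 / fs,
              by = 1000 / fs)
  n <- length(t_ms)
  nch <- array$n_channels
  if (is.null(mixing)) mixing <- make_noise_mixing(array, params$noise)
  epoch <- matrix(0, nch, n)

  for (e in params$effects) {
    if (e$window_ms[1] < params$epoch_ms[1] || e$window_ms[2] > params$epoch_ms[2])
      stop("effect window outside the epoch: ", e$label)
    sc <- if (!is.null(amp_scale) && !is.null(amp_scale[[e$label]]))
      amp_scale[[e$label]] else 1
    amp <- sc * if (condition == "correct") e$amp_correct else e$amp_incorrect
    if (e$kind == "erf_sustained") {
      amp <- amp * exp(stats::rnorm(1, 0, params$trial_sd / 2))
      tc <- smooth_boxcar(t_ms, e$window_ms[1], e$window_ms[2], 250) * amp
      epoch <- epoch + tcrossprod(e$topography, tc)
    } else if (e$kind == "steady_state") {
      amp <- amp * exp(stats::rnorm(1, 0, params$trial_sd))
      tc <- steady_state_course(e$rate_hz, t_ms, fs, params$ss_model) * amp
      epoch <- epoch + tcrossprod(e$topography, tc)
    } else { # band_power
      x <- bandlimited_noise(n, 1, fs, e$band[1], e$band[2])[, 1]
      envl <- e$base + (amp - e$base) *
        smooth_boxcar(t_ms, e$window_ms[1], e$window_ms[2], 150)
      epoch <- epoch + tcrossprod(e$topography, envl * x)
    }
  }

  ns <- params$noise
  if (ns$one_over_f_scale > 0) {
    lat <- colored_noise(n, ns$n_latent, ns$one_over_f_exp)
    epoch <- epoch + (mixing$background %*% t(lat)) *
      (ns$one_over_f_scale / sqrt(ns$n_latent))
  }
  if (ns$line_scale > 0) {
    ph <- stats::runif(1, 0, 2 * pi)
    line <- sin(2 * pi * ns$line_hz * t_ms / 1000 + ph) * sqrt(2)
    epoch <- epoch + tcrossprod(mixing$line, line) * ns$line_scale
  }
  if (ns$drift_scale > 0) {
    dr <- vapply(1:3, function(i) {
      d <- cumsum(cumsum(stats::rnorm(n)))
      d / stats::sd(d)
    }, numeric(n))
    epoch <- epoch + (mixing$drift %*% t(dr)) * (ns$drift_scale / sqrt(3))
  }
  if (ns$sensor_scale > 0) {
    epoch <- epoch + matrix(stats::rnorm(nch * n, sd = ns$sensor_scale), nch, n)
  }
  epoch
}

#' Simulate the behavioural response to one trial
#'
#' @param trial_class `"same"` or `"different"`.
#' @param probe_rate 3, 7 or 19.
#' @param behavior A [behavior_params()] list.
#' @return List with `response`, `outcome` (TP/TN/FP/FN) and `rt_ms`.
#' @export
simulate_behavior <- function(trial_class, probe_rate, behavior) {
  r <- as.character(probe_rate)
  p_same <- if (trial_class == "same") behavior$p_hit[[r]] else behavior$p_fa[[r]]
  if (probe_rate == 3) p_same <- p_same + behavior$bias_3hz
  if (p_same < 0 || p_same > 1) stop("response probability outside [0, 1]")
  response <- if (stats::runif(1) < p_same) "same" else "different"
  outcome <- classify_outcome(trial_class, response)
  mu <- behavior$rt_meanlog[[outcome]]
  if (probe_rate == 3) mu <- mu + behavior$rt_rate_mod[[outcome]]
  rt <- stats::rlnorm(1, meanlog = mu, sdlog = behavior$rt_sdlog)
  list(response = response, outcome = outcome, rt_ms = rt)
}

#' Outcome from trial class and response
#'
#' TP: same trial, "same" response; FN: same trial, "different" response;
#' TN: different trial, "different" response; FP: different trial, "same".
#'
#' @param trial_class `"same"` or `"different"` (vectorized).
#' @param response `"same"` or `"different"` (vectorized).
#' @export
classify_outcome <- function(trial_class, response) {
  ifelse(trial_class == "same",
         ifelse(response == "same", "TP", "FN"),
         ifelse(response == "same", "FP", "TN"))
}

#' Simulate one participant
#'
#' Generates the schedule, behavioural table and epoch set for a single
#' participant. Epochs are labelled correct/incorrect according to the
#' simulated behavioural outcome, so planted condition effects and behaviour
#' are consistent.
#'
#' @param array A `sensor_array`.
#' @param params A [sim_params()] list.
#' @param n_per_cell Trials per (probe rate x class) cell.
#' @param seed Participant seed.
#' @param participant_id Identifier.
#' @param amp_scale Optional named per-effect amplitude scaling (random
#'   participant effect); default drawn log-normally with SD
#'   `params$participant_sd`.
#' @return List with `epochs` (`epoch_set`), `behavior` (data frame) and
#'   `schedule`.
#' @export
simulate_participant <- function(array, params, n_per_cell = 56, seed = 1L,
                                 participant_id = "P01", amp_scale = NULL) {
  schedule <- make_trial_schedule(n_per_cell, seed = derive_seed(seed, "sched"),
                                  participant_id = participant_id)
  local_rng(derive_seed(seed, "data"))
  if (is.null(amp_scale)) {
    labs <- vapply(params$effects, `[[`, "", "label")
    amp_scale <- stats::setNames(
      as.list(exp(stats::rnorm(length(labs), 0, params$participant_sd))), labs)
  }
  mixing <- make_noise_mixing(array, params$noise)
  nt <- nrow(schedule)
  beh <- vector("list", nt)
  fs <- params$fs_hz
  nsamp <- round((params$epoch_ms[2] - params$epoch_ms[1]) / 1000 * fs)
  dat <- array(0, dim = c(nt, array$n_channels, nsamp))
  for (i in seq_len(nt)) {
    b <- simulate_behavior(schedule$class[i], schedule$probe_rate[i],
                           params$behavior)
    beh[[i]] <- data.frame(trial_index = i, class = schedule$class[i],
                           probe_rate = schedule$probe_rate[i],
                           response = b$response, outcome = b$outcome,
                           rt_ms = b$rt_ms, stringsAsFactors = FALSE)
    condition <- if (b$outcome %in% c("TP", "TN")) "correct" else "incorrect"
    dat[i, , ] <- simulate_trial_signal(condition, params, array,
                                        mixing = mixing, amp_scale = amp_scale)
  }
  behavior <- do.call(rbind, beh)
  behavior$participant_id <- participant_id
  epochs <- epoch_set(dat, fs, params$epoch_ms[1],
                      channel_ids = array$channel_ids)
  list(epochs = epochs, behavior = behavior, schedule = schedule)
}

#' Simulate a full study
#'
#' Generates `n_participants` independent participants (independent child
#' seeds from the master seed; per-participant random scaling of effect
#' amplitudes) and writes each participant's epoch container and behaviour
#' CSV to `outdir` incrementally, keeping at most one participant in memory.
#' A drawn participant with fewer correct than incorrect trials (or none of
#' either) is replaced by a fresh draw, mirroring the study's exclusion of
#' participants unable to perform the task; the analysis pipeline assumes a
#' correct-trial majority when equating trial counts.
#'
#' @param n_participants Number of participants (study value 23).
#' @param array A `sensor_array`.
#' @param params A [sim_params()] list.
#' @param n_per_cell Trials per cell.
#' @param seed Master seed.
#' @param outdir Output directory (created if needed).
#' @return Data frame manifest: participant_id, epoch and behaviour paths.
#' @export
simulate_study <- function(n_participants, array, params, n_per_cell = 56,
                           seed = 1L, outdir = tempfile("astmeg_study")) {
  if (n_participants < 2) stop("n_participants must be >= 2")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    for (attempt in 0:9) {
      sim <- simulate_participant(array, params, n_per_cell,
                                  seed = derive_seed(seed, "participant",
                                                     p + 1000 * attempt),
                                  participant_id = pid)
      n_cor <- sum(sim$behavior$outcome %in% c("TP", "TN"))
      n_inc <- nrow(sim$behavior) - n_cor
      if (n_inc >= 1 && n_cor >= n_inc) break
    }
    epath <- file.path(outdir, paste0(pid, ".epo.rds"))
    bpath <- file.path(outdir, paste0(pid, "_behavior.csv"))
    write_epochs(sim$epochs, epath)
    utils::write.csv(sim$behavior, bpath, row.names = FALSE)
    rows[[p]] <- data.frame(participant_id = pid, epochs = epath,
                            behavior = bpath, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
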
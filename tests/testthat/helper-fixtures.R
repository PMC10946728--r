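# Shared fixtures, memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small sensor array used across tests.
tiny_array <- function(n = 32) {
  memo(paste0("array", n), make_sensor_array(n, seed = 1))
}

# One simulated participant at miniature scale (fast; default effects).
mini_participant <- function() {
  memo("mini_participant", {
    arr <- tiny_array(32)
    params <- sim_params(fs_hz = 120, effects = default_effects(arr), seed = 3)
    simulate_participant(arr, params, n_per_cell = 5, seed = 11)
  })
}

# Epochs with a single planted phase-locked source under heavy
# non-phase-locked noise (for DSS tests).
planted_source_epochs <- function(n_trials = 40, nch = 24, fs = 150,
                                  noise_sd = 2, seed = 42) {
  set.seed(seed)
  arr <- make_sensor_array(nch, seed = 2)
  nsamp <- round(7 * fs)
  t_ms <- seq(-1000, 6000 - 1000 / fs, by = 1000 / fs)
  src <- sin(2 * pi * 3 * t_ms / 1000) * smooth_boxcar(t_ms, 0, 2500, 100)
  topo <- make_topography(arr, c(pi, 0.4), 0.5)
  dat <- array(0, c(n_trials, nch, nsamp))
  for (i in seq_len(n_trials)) {
    dat[i, , ] <- tcrossprod(topo, src) +
      matrix(rnorm(nch * nsamp, sd = noise_sd), nch, nsamp)
  }
  list(epochs = epoch_set(dat, fs), source = src, topo = topo, array = arr)
}

# smooth_boxcar and other internal helpers are available because tests run
# with the package namespace attached via load_package = "installed"; pull
# the internals we use explicitly:
smooth_boxcar <- astmeg:::smooth_boxcar
hann_window <- astmeg:::hann_window
steady_state_course <- astmeg:::steady_state_course
colored_noise <- astmeg:::colored_noise
bandlimited_noise <- astmeg:::bandlimited_noise
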
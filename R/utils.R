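# Internal helpers shared across modules.

# Seed the RNG if a seed is given. Functions taking a `seed` argument are
# fully reproducible from it; passing NULL leaves the RNG state alone.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter scheme used to give every participant and pipeline
#' stage an independent, reproducible RNG stream. Stays below 2^31 - 1.
#'
#' @param master Master seed (integer).
#' @param stage Stage label (character) or integer tag.
#' @param index Counter within the stage (e.g. participant number).
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage = "stage", index = 0L) {
  tag <- if (is.character(stage)) sum(utf8ToInt(paste(stage, collapse = ""))) else as.numeric(stage)
  x <- (as.numeric(master) * 48271 + tag * 69621 + as.numeric(index) * 16807) %% 2147483563
  as.integer(x) + 1L
}

# Periodic Hann window of length n (matches FFT-taper conventions).
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
}

# Boxcar over [start_ms, end_ms) with raised-cosine edges of `ramp_ms`,
# evaluated at times t_ms. Edges are contained inside the window.
smooth_boxcar <- function(t_ms, start_ms, end_ms, ramp_ms = 100) {
  g <- numeric(length(t_ms))
  inside <- t_ms >= start_ms & t_ms < end_ms
  g[inside] <- 1
  if (ramp_ms > 0) {
    u <- t_ms - start_ms
    rise <- inside & u < ramp_ms
    g[rise] <- 0.5 * (1 - cos(pi * u[rise] / ramp_ms))
    v <- end_ms - t_ms
    fall <- inside & v < ramp_ms & !(u < ramp_ms)
    g[fall] <- 0.5 * (1 - cos(pi * v[fall] / ramp_ms))
  }
  g
}

# Sample indices (1-based) of a half-open time window [start_ms, end_ms)
# given epoch start t0_ms and sampling rate.
window_indices <- function(t0_ms, fs_hz, n_samples, start_ms, end_ms) {
  t_ms <- t0_ms + (seq_len(n_samples) - 1) / fs_hz * 1000
  which(t_ms >= start_ms & t_ms < end_ms)
}

# Time axis in ms for an epoch.
epoch_times <- function(t0_ms, fs_hz, n_samples) {
  t0_ms + (seq_len(n_samples) - 1) / fs_hz * 1000
}
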
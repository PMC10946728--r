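# Time-frequency analysis: sliding-window single-Hanning-taper spectrogram,
# relative-change baseline normalization, band averaging, and band x stage
# cluster permutation tests.

#' Sliding-window Hanning spectrogram power
#'
#' Computes power from `fmin` to `fmax` Hz in `fstep` steps with a fixed
#' `window_ms` single Hanning taper sliding in `step_ms` increments. Each
#' segment is mean-removed before tapering (so sustained fields do not leak
#' into the lowest bins) and zero-padded to `fs / fstep` samples so the FFT
#' grid lands exactly on the requested frequency step. Power is averaged over trials (the unit in
#' which all downstream statistics operate) unless `keep_trials = TRUE`.
#'
#' @param epochs An `epoch_set`.
#' @param fmin,fmax,fstep Frequency grid (defaults 1-30 Hz in 0.5-Hz steps,
#'   59 bins).
#' @param window_ms Taper length (study value 400 ms).
#' @param step_ms Slide increment between window centres (default 50 ms).
#' @param keep_trials Return per-trial power (memory-heavy) instead of the
#'   trial average.
#' @return A `tfr`: `power` (channels x freqs x times, or trials x channels x
#'   freqs x times), `freqs`, `times_ms` (window centres), `window_ms`,
#'   `fs_hz`, `n_trials`, `normalized`.
#' @export
stft_power <- function(epochs, fmin = 1, fmax = 30, fstep = 0.5,
                       window_ms = 400, step_ms = 50, keep_trials = FALSE) {
  fs <- epochs$fs_hz
  d <- dim(epochs$data)
  nwin <- round(window_ms / 1000 * fs)
  if (nwin > d[3]) stop("taper window longer than the epoch")
  nfft <- round(fs / fstep)
  freqs <- seq(fmin, fmax, by = fstep)
  bin <- round(freqs / fstep) + 1L
  if (any(bin > nfft)) stop("fmax exceeds the padded FFT grid")
  taper <- hann_window(nwin)
  # power normalization: one-sided PSD-style scaling (arbitrary fixed unit)
  pscale <- 2 / (fs * sum(taper^2))

  t_ms <- epoch_times(epochs$t0_ms, fs, d[3])
  half <- window_ms / 2
  centers <- t_ms[t_ms >= t_ms[1] + half & t_ms <= t_ms[d[3]] - half + 1000 / fs]
  centers <- centers[seq(1, length(centers), by = max(1L, round(step_ms / 1000 * fs)))]
  nc <- length(centers)
  ntr <- d[1]; nch <- d[2]; nf <- length(freqs)

  out <- if (keep_trials) array(0, c(ntr, nch, nf, nc)) else array(0, c(nch, nf, nc))
  # chunk trials to bound the FFT matrix size
  max_cols <- 30000L
  tr_block <- max(1L, min(ntr, floor(max_cols / nch)))
  starts <- seq(1L, ntr, by = tr_block)
  for (ci in seq_len(nc)) {
    i0 <- which.min(abs(t_ms - (centers[ci] - half)))
    i0 <- min(max(i0, 1L), d[3] - nwin + 1L)
    seg_idx <- i0:(i0 + nwin - 1L)
    for (s0 in starts) {
      tr <- s0:min(s0 + tr_block - 1L, ntr)
      seg <- epochs$data[tr, , seg_idx, drop = FALSE]        # tr x ch x nwin
      m <- matrix(aperm(seg, c(3, 1, 2)), nrow = nwin)       # nwin x (tr*ch)
      m <- m - rep(colMeans(m), each = nwin)                 # per-segment demean
      m <- m * taper
      padded <- matrix(0, nfft, ncol(m))
      padded[seq_len(nwin), ] <- m
      sp <- stats::mvfft(padded)[bin, , drop = FALSE]        # nf x (tr*ch)
      pw <- (Mod(sp)^2) * pscale
      pw_arr <- array(pw, c(nf, length(tr), nch))            # nf x tr x ch
      if (keep_trials) {
        out[tr, , , ci] <- aperm(pw_arr, c(2, 3, 1))
      } else {
        out[, , ci] <- out[, , ci] + t(colMeans(aperm(pw_arr, c(2, 1, 3)))) *
          (length(tr) / ntr)
      }
    }
  }
  structure(list(power = out, freqs = freqs, times_ms = centers,
                 window_ms = window_ms, fs_hz = fs, n_trials = ntr,
                 keep_trials = keep_trials, normalized = FALSE,
                 baseline = NULL),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("TFR: %s, %d freqs (%g-%g Hz), %d time centres (%g to %g ms)%s\n",
              paste(dim(x$power), collapse = " x "), length(x$freqs),
              min(x$freqs), max(x$freqs), length(x$times_ms),
              min(x$times_ms), max(x$times_ms),
              if (x$normalized) ", baseline-normalized" else ""))
  invisible(x)
}

#' Baseline-normalize a TFR (relative change)
#'
#' Per channel and frequency, expresses trial-averaged power as relative
#' change (P - B) / B, where B is the mean power over window centres falling
#' in the baseline interval (study value -400 to -200 ms, i.e. data from
#' -600 to 0 ms with a 400-ms window).
#'
#' @param tfr A trial-averaged `tfr`.
#' @param window_ms Baseline centre interval (inclusive).
#' @param mode `"relchange"` (default) or `"db"` (10 log10(P / B)).
#' @return A normalized `tfr`.
#' @export
baseline_normalize_tfr <- function(tfr, window_ms = c(-400, -200),
                                   mode = c("relchange", "db")) {
  mode <- match.arg(mode)
  if (tfr$keep_trials) stop("normalize the trial-averaged TFR (keep_trials = FALSE)")
  bl <- which(tfr$times_ms >= window_ms[1] & tfr$times_ms <= window_ms[2])
  if (!length(bl)) stop("no window centres inside the baseline interval")
  B <- apply(tfr$power[, , bl, drop = FALSE], c(1, 2), mean)
  if (any(B == 0)) stop("zero baseline power; cannot normalize")
  out <- tfr
  out$power <- if (mode == "relchange") {
    sweep(tfr$power, c(1, 2), B, "/") - 1
  } else {
    10 * log10(sweep(tfr$power, c(1, 2), B, "/"))
  }
  out$normalized <- TRUE
  out$baseline <- list(window_ms = window_ms, mode = mode)
  out
}

#' Average TFR power over a frequency band
#'
#' @param tfr A trial-averaged `tfr`.
#' @param band `c(f_lo, f_hi)` Hz; band edges inclusive. Canonical bands:
#'   delta 1-4, theta 4-7, alpha 8-13, low beta 14-20 Hz.
#' @return channels x time matrix.
#' @export
band_power <- function(tfr, band) {
  sel <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(sel)) stop("band [", band[1], ", ", band[2], "] is empty on the grid")
  apply(tfr$power[, sel, , drop = FALSE], c(1, 3), mean)
}

#' Canonical frequency bands (Hz)
#' @export
canonical_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 7), alpha = c(8, 13), beta = c(14, 20))
}

#' Band x stage cluster permutation test on TFRs
#'
#' Restricts each participant's per-condition band-power map to window
#' centres within the stage, then runs the channel x time cluster permutation
#' test (spatial adjacency plus temporal adjacency of consecutive centres).
#'
#' @param correct,incorrect Lists of normalized `tfr` objects, one per
#'   participant, same order.
#' @param band `c(f_lo, f_hi)` Hz.
#' @param stage Stage name or `c(start, end)` ms window (applied to window
#'   centres, half-open).
#' @param array A `sensor_array`.
#' @param stages Stage window lookup.
#' @param ... Passed to [permutation_cluster_test()].
#' @return A `cluster_result` with an extra `times_ms` field (the centres
#'   tested).
#' @export
tfr_stage_cluster_test <- function(correct, incorrect, band, stage, array,
                                   stages = default_stages(), ...) {
  stopifnot(length(correct) == length(incorrect), length(correct) >= 2)
  win <- if (is.character(stage)) stages[[stage]] else stage
  tms <- correct[[1]]$times_ms
  sel <- which(tms >= win[1] & tms < win[2])
  if (!length(sel)) stop("no window centres inside the stage")
  np <- length(correct)
  nch <- dim(correct[[1]]$power)[1]
  a <- array(0, c(np, nch, length(sel)))
  b <- array(0, c(np, nch, length(sel)))
  for (p in seq_len(np)) {
    a[p, , ] <- band_power(correct[[p]], band)[, sel]
    b[p, , ] <- band_power(incorrect[[p]], band)[, sel]
  }
  res <- permutation_cluster_test(a, b, array$adjacency, ...)
  res$times_ms <- tms[sel]
  res
}

#' Time span (ms) of a cluster from a channel x time test
#'
#' @param cluster One element of a `cluster_result$clusters` list from
#'   [tfr_stage_cluster_test()].
#' @param result The `cluster_result` it came from (for `times_ms` and map
#'   dimensions).
#' @return `c(start, end)` ms of the window centres the cluster spans.
#' @export
cluster_time_span <- function(cluster, result) {
  nch <- nrow(result$t_map)
  tt <- (cluster$nodes - 1L) %/% nch + 1L
  range(result$times_ms[tt])
}
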
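# Steady-state fidelity analysis: per-stage trial concatenation, fine-grid
# power spectral density, neighbour-bin normalization, top-channel selection,
# peak extraction at the stimulation rates, and the condition x rate ANOVA.

#' Concatenate the stage segments of all trials
#'
#' Joins each trial's stage segment end-to-end (in trial order) into one long
#' series per channel, maximizing spectral resolution: 20 encoding segments
#' of 2.5 s at 600 Hz give 30,000 samples and hence 0.02-Hz bin spacing.
#'
#' @param epochs An `epoch_set`.
#' @param stage Stage name or `c(start, end)` ms window.
#' @return channels x (n_trials * stage_samples) matrix.
#' @export
concatenate_stage <- function(epochs, stage) {
  if (n_trials(epochs) < 1) stop("no trials")
  idx <- stage_indices(epochs, stage)
  arr <- epochs$data[, , idx, drop = FALSE]       # trials x ch x len
  out <- aperm(arr, c(2, 3, 1))                   # ch x len x trials
  dim(out) <- c(dim(arr)[2], dim(arr)[3] * dim(arr)[1])
  out
}

#' Single-taper PSD of a long series
#'
#' One Hanning taper over the whole (concatenated) series; power is the
#' squared FFT magnitude on the native grid (spacing fs / n_samples),
#' restricted to `f_range`.
#'
#' @param series channels x samples matrix (or a single series vector), at
#'   least 1 s long.
#' @param fs Sampling rate.
#' @param f_range Analysis range in Hz (study value 1-21).
#' @return List with `freqs` and `power` (channels x bins).
#' @export
psd_spectrum <- function(series, fs, f_range = c(1, 21)) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  n <- ncol(series)
  if (n < fs) stop("series must be at least 1 s long")
  taper <- hann_window(n)
  x <- t(series - rowMeans(series)) * taper       # n x ch
  X <- stats::mvfft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- which(freqs >= f_range[1] & freqs <= f_range[2])
  power <- t(Mod(X[sel, , drop = FALSE])^2) * (2 / (fs * sum(taper^2)))
  list(freqs = freqs[sel], power = power)
}

#' Neighbour-bin normalization of a spectrum
#'
#' Divides the power at each frequency bin by the mean power across its 3rd
#' to 20th neighbouring bins above and below (a local signal-to-noise
#' spectrum: flat regions map to ~1, narrow peaks to their height above the
#' local floor). Offsets falling outside the spectrum use only the available
#' side.
#'
#' @param power channels x bins matrix (or vector).
#' @param j_lo,j_hi Neighbour offset range (study values 3 and 20).
#' @return Normalized matrix of the same shape.
#' @export
normalize_spectrum <- function(power, j_lo = 3, j_hi = 20) {
  vec <- is.null(dim(power))
  if (vec) power <- matrix(power, nrow = 1)
  nb <- ncol(power)
  if (nb <= j_lo) stop("spectrum too short for the neighbour window")
  acc <- matrix(0, nrow(power), nb)
  cnt <- numeric(nb)
  for (o in j_lo:j_hi) {
    lo_ok <- (1 + o):nb
    acc[, lo_ok - o] <- acc[, lo_ok - o] + power[, lo_ok]   # neighbours above
    cnt[lo_ok - o] <- cnt[lo_ok - o] + 1
    acc[, lo_ok] <- acc[, lo_ok] + power[, lo_ok - o]       # neighbours below
    cnt[lo_ok] <- cnt[lo_ok] + 1
  }
  if (any(cnt == 0)) stop("bins without any valid neighbours")
  floor_mean <- acc / rep(cnt, each = nrow(power))
  out <- power / floor_mean
  if (vec) out[1, ] else out
}

#' Select the top-k channels at a frequency
#'
#' Ranks channels by the mean of the two conditions' normalized PSD at the
#' bin nearest `freq` and returns the top `k` (ties broken by channel index).
#'
#' @param norm_correct,norm_incorrect channels x bins normalized spectra.
#' @param freqs Frequency grid of the spectra.
#' @param freq Target frequency (Hz).
#' @param k Number of channels (study value 10; capped at n_channels).
#' @param mode `"mean"` (default) or `"max"` across the two conditions.
#' @return Integer channel indices, best first.
#' @export
select_top_channels <- function(norm_correct, norm_incorrect, freqs, freq,
                                k = 10, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  bin <- which.min(abs(freqs - freq))
  score <- if (mode == "mean") {
    (norm_correct[, bin] + norm_incorrect[, bin]) / 2
  } else {
    pmax(norm_correct[, bin], norm_incorrect[, bin])
  }
  k <- min(k, length(score))
  order(score, decreasing = TRUE)[seq_len(k)]
}

#' Band-limited spectral SNR around a target frequency
#'
#' Mean normalized PSD over the bins within `halfwidth` Hz of a target
#' frequency: ~1 where the spectrum is locally flat, clearly above 1 when a
#' narrow peak (or its immediate comb lines, for concatenated trial spectra)
#' is present near the target.
#'
#' @param norm channels x bins normalized spectrum (or a vector).
#' @param freqs Frequency grid.
#' @param freq Target frequency (Hz).
#' @param halfwidth Window half-width (Hz).
#' @return Per-channel mean (vector), or a scalar for vector input.
#' @export
psd_band_snr <- function(norm, freqs, freq, halfwidth = 0.25) {
  sel <- which(abs(freqs - freq) <= halfwidth)
  if (!length(sel)) sel <- which.min(abs(freqs - freq))
  if (is.null(dim(norm))) mean(norm[sel]) else rowMeans(norm[, sel, drop = FALSE])
}

#' Per-participant PSD peak table at the stimulation rates
#'
#' For each stimulation rate, locates the peak bin (the bin with the largest
#' condition- and channel-mean normalized PSD within `halfwidth` Hz of the
#' nominal rate; concatenated-trial spectra put the steady-state lines on the
#' trial-period comb, a fraction of a bin away from the nominal frequency),
#' selects the top-`k` channels across both conditions at that bin, and
#' returns the mean normalized PSD over those channels per condition, plus
#' the band SNR (see [psd_band_snr()]) used for peak-presence checks.
#'
#' @param norm_correct,norm_incorrect channels x bins normalized spectra of
#'   the two conditions.
#' @param freqs Frequency grid.
#' @param rates Stimulation rates (default 3, 7, 19 Hz).
#' @param k Channels per selection.
#' @param mode Channel-ranking mode (see [select_top_channels()]).
#' @param halfwidth Peak search half-width in Hz (0 reads the bin nearest
#'   the nominal rate).
#' @return Data frame: rate, peak_freq, correct, incorrect, snr_correct,
#'   snr_incorrect, channels (list column of selected channel indices).
#' @export
psd_peak_table <- function(norm_correct, norm_incorrect, freqs,
                           rates = c(3, 7, 19), k = 10, mode = "mean",
                           halfwidth = 0.25) {
  rows <- lapply(rates, function(r) {
    sel <- which(abs(freqs - r) <= halfwidth)
    if (!length(sel)) sel <- which.min(abs(freqs - r))
    prof <- colMeans(norm_correct[, sel, drop = FALSE] +
                       norm_incorrect[, sel, drop = FALSE])
    bin <- sel[which.max(prof)]
    ch <- select_top_channels(norm_correct, norm_incorrect, freqs,
                              freqs[bin], k, mode)
    data.frame(rate = r, peak_freq = freqs[bin],
               correct = mean(norm_correct[ch, bin]),
               incorrect = mean(norm_incorrect[ch, bin]),
               snr_correct = mean(psd_band_snr(norm_correct, freqs, r,
                                               max(halfwidth, 0.05))[ch]),
               snr_incorrect = mean(psd_band_snr(norm_incorrect, freqs, r,
                                                 max(halfwidth, 0.05))[ch]))
  })
  out <- do.call(rbind, rows)
  out$channels <- lapply(seq_along(rates), function(i) {
    r <- rows[[i]]
    select_top_channels(norm_correct, norm_incorrect, freqs, r$peak_freq,
                        k, mode)
  })
  out
}

#' Full per-participant PSD analysis of one stage
#'
#' Projects the participant's epochs onto the first `dss_keep` DSS components
#' (determined from the encoding stage), concatenates the stage segments per
#' condition, and returns neighbour-normalized spectra plus the peak table.
#'
#' @param correct,incorrect `epoch_set`s of the two conditions (equated).
#' @param stage Stage name or window.
#' @param dss_keep Leading DSS components to retain (study value 2); set to
#'   `NULL` to skip the DSS projection.
#' @param f_range Analysis range (Hz).
#' @param k Channels per peak selection.
#' @return List: `freqs`, `norm_correct`, `norm_incorrect`, `peaks`.
#' @export
psd_participant <- function(correct, incorrect, stage = "encoding",
                            dss_keep = 2, f_range = c(1, 21), k = 10) {
  # peak-presence summary from unprojected sensor spectra: after a rank-2
  # DSS projection all channels share two time courses, so single-bin
  # normalized values are too variable for a stable presence statistic;
  # the full sensor array provides the spatial averaging
  raw_c <- normalize_spectrum(
    psd_spectrum(concatenate_stage(correct, stage), correct$fs_hz, f_range)$power)
  raw_sp <- psd_spectrum(concatenate_stage(incorrect, stage),
                         incorrect$fs_hz, f_range)
  raw_i <- normalize_spectrum(raw_sp$power)
  snr <- data.frame(rate = c(3, 7, 19))
  snr$snr <- vapply(snr$rate, function(r)
    mean(psd_band_snr((raw_c + raw_i) / 2, raw_sp$freqs, r)), 0)

  if (!is.null(dss_keep)) {
    pooled <- epoch_set(
      abind_trials(correct$data, incorrect$data), correct$fs_hz,
      correct$t0_ms, correct$channel_ids, stages = correct$stages)
    model <- dss_decompose(pooled, "encoding")
    correct <- dss_denoise(correct, model, dss_keep)
    incorrect <- dss_denoise(incorrect, model, dss_keep)
  }
  sp_c <- psd_spectrum(concatenate_stage(correct, stage), correct$fs_hz, f_range)
  sp_i <- psd_spectrum(concatenate_stage(incorrect, stage), incorrect$fs_hz, f_range)
  nc <- normalize_spectrum(sp_c$power)
  ni <- normalize_spectrum(sp_i$power)
  list(freqs = sp_c$freqs, norm_correct = nc, norm_incorrect = ni,
       peaks = psd_peak_table(nc, ni, sp_c$freqs, k = k),
       snr = snr)
}

# Bind two trials x ch x time arrays along the trial dimension.
abind_trials <- function(a, b) {
  stopifnot(identical(dim(a)[-1], dim(b)[-1]))
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Condition x rate ANOVA on PSD peaks
#'
#' Two-way repeated-measures ANOVA (condition: correct/incorrect; rate: 3, 7,
#' 19 Hz) on the per-participant peak table.
#'
#' @param peaks Either a participants x 2 x 3 array (condition x rate) or a
#'   list of per-participant peak tables from [psd_peak_table()].
#' @return An `anova_result` (see [rm_anova_2way()]).
#' @export
psd_peak_anova <- function(peaks) {
  if (is.list(peaks) && !is.array(peaks)) {
    np <- length(peaks)
    cube <- array(0, c(np, 2, 3),
                  dimnames = list(NULL, c("correct", "incorrect"),
                                  c("3", "7", "19")))
    for (p in seq_len(np)) {
      cube[p, 1, ] <- peaks[[p]]$correct
      cube[p, 2, ] <- peaks[[p]]$incorrect
    }
    peaks <- cube
  }
  rm_anova_2way(peaks, names_ab = c("condition", "rate"))
}
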
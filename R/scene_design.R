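# Trial and stimulus design for the three-stream tone-pip task.
#
# Each trial presents an auditory "scene" of three simultaneous streams of
# repetitive pure tones (rates 3, 7 and 19 Hz, each with a distinct carrier
# frequency), followed by a silent maintenance interval and a single-stream
# probe that is either identical to one scene stream ("same") or a novel
# carrier-rate pairing of scene elements ("different").

# Printed design constants: SOA and tone duration per rate (ms). The tone
# duration is exactly half the SOA; the 19-Hz SOA is the design's printed
# 52.3 ms, not 1000/19.
.stream_params <- data.frame(
  rate_hz     = c(3, 7, 19),
  soa_ms      = c(333, 142.9, 52.3),
  tone_dur_ms = c(166.5, 71.45, 26.15)
)

#' Carrier-frequency pool
#'
#' The fixed pool of 11 pure-tone carrier frequencies (Hz) used to build
#' auditory scenes. The printed values are used verbatim; successive ratios
#' are close to, but not exactly, a geometric progression.
#'
#' @return Numeric vector of 11 strictly increasing frequencies in Hz.
#' @export
build_frequency_pool <- function() {
  c(200, 292, 405.1, 542, 708.4, 910.7, 1157, 1456, 1820, 2262, 2799)
}

#' Stream timing parameters for a stimulation rate
#'
#' @param rate_hz One of 3, 7 or 19.
#' @return List with `rate_hz`, `soa_ms`, `tone_dur_ms`.
#' @export
stream_timing <- function(rate_hz) {
  i <- match(rate_hz, .stream_params$rate_hz)
  if (is.na(i)) stop("rate_hz must be one of 3, 7, 19")
  as.list(.stream_params[i, ])
}

#' Build a balanced trial schedule
#'
#' Constructs a randomized, fully balanced schedule: `6 * n_per_cell` trials,
#' with `n_per_cell` trials for every probe-rate (3/7/19 Hz) by trial-class
#' (same/different) cell. Per trial, three carriers are drawn without
#' replacement from the 11-value pool and randomly paired with the rates
#' 3, 7 and 19 Hz. In a "same" trial the probe duplicates the scene stream at
#' the probe rate; in a "different" trial the probe carrier is one of the two
#' scene carriers that was *not* paired with the probe rate. Inter-trial
#' intervals are drawn uniformly from 700 to 2000 ms in 100-ms steps.
#'
#' @param n_per_cell Trials per (probe rate x class) cell; the study design
#'   uses 56, giving 336 trials.
#' @param seed Integer seed; the schedule is fully reproducible from it.
#' @param participant_id Optional identifier stored with the schedule.
#' @return A `trial_schedule`: data frame with one row per trial and columns
#'   `trial_index`, `class`, `carrier_3`, `carrier_7`, `carrier_19`,
#'   `probe_rate`, `probe_carrier`, `iti_ms`, plus attributes `seed` and
#'   `participant_id`.
#' @export
make_trial_schedule <- function(n_per_cell = 56, seed = 1L, participant_id = "P01") {
  if (!is.numeric(n_per_cell) || length(n_per_cell) != 1 ||
      n_per_cell < 1 || n_per_cell != round(n_per_cell)) {
    stop("n_per_cell must be a positive integer")
  }
  rng <- local_rng(seed)
  pool <- build_frequency_pool()
  rates <- c(3, 7, 19)
  cells <- expand.grid(probe_rate = rates, class = c("same", "different"),
                       stringsAsFactors = FALSE)
  n_trials <- 6L * as.integer(n_per_cell)
  cell_idx <- rep(seq_len(nrow(cells)), each = n_per_cell)

  carriers <- t(vapply(seq_len(n_trials), function(i) sample(pool, 3L), numeric(3)))
  # random pairing of the three drawn carriers with rates 3/7/19
  perm <- t(vapply(seq_len(n_trials), function(i) sample.int(3L), integer(3)))
  assigned <- cbind(carriers[cbind(seq_len(n_trials), perm[, 1])],
                    carriers[cbind(seq_len(n_trials), perm[, 2])],
                    carriers[cbind(seq_len(n_trials), perm[, 3])])
  colnames(assigned) <- c("carrier_3", "carrier_7", "carrier_19")

  probe_rate <- cells$probe_rate[cell_idx]
  class <- cells$class[cell_idx]
  rate_col <- match(probe_rate, rates)
  probe_carrier <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    if (class[i] == "same") {
      probe_carrier[i] <- assigned[i, rate_col[i]]
    } else {
      # one of the two carriers NOT paired with the probe rate
      others <- assigned[i, -rate_col[i]]
      probe_carrier[i] <- others[sample.int(2L, 1L)]
    }
  }
  iti_ms <- sample(seq(700, 2000, by = 100), n_trials, replace = TRUE)
  ord <- sample.int(n_trials)

  sched <- data.frame(
    trial_index = seq_len(n_trials),
    class = class[ord],
    carrier_3 = assigned[ord, 1],
    carrier_7 = assigned[ord, 2],
    carrier_19 = assigned[ord, 3],
    probe_rate = probe_rate[ord],
    probe_carrier = probe_carrier[ord],
    iti_ms = iti_ms[ord],
    stringsAsFactors = FALSE
  )
  attr(sched, "seed") <- seed
  attr(sched, "participant_id") <- participant_id
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("Trial schedule: %d trials (participant %s, seed %s)\n",
              nrow(x), attr(x, "participant_id"), attr(x, "seed")))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Write / read a trial schedule as CSV
#'
#' @param schedule A `trial_schedule`.
#' @param path Output CSV path.
#' @export
write_trial_schedule <- function(schedule, path) {
  df <- as.data.frame(schedule)
  df$seed <- attr(schedule, "seed")
  df$participant_id <- attr(schedule, "participant_id")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_schedule
#' @param path Input CSV path.
#' @export
read_trial_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  seed <- df$seed[1]; pid <- df$participant_id[1]
  df$seed <- NULL; df$participant_id <- NULL
  attr(df, "seed") <- seed
  attr(df, "participant_id") <- pid
  class(df) <- c("trial_schedule", "data.frame")
  df
}

#' Synthesize a tone-pip train
#'
#' Generates the amplitude envelope (or, with `with_carrier = TRUE`, the
#' pure-tone waveform) of a single repetitive tone-pip stream. Tones of
#' `tone_dur_ms` start at 0, SOA, 2*SOA, ...; each tone carries 5-ms
#' raised-cosine onset and offset ramps counted inside the tone duration.
#' A final tone whose offset would exceed `duration_ms` is omitted entirely.
#'
#' @param rate_hz Stream rate: 3, 7 or 19.
#' @param duration_ms Series duration in ms (> 0).
#' @param fs_hz Sampling rate; must exceed twice the stream rate in envelope
#'   mode and twice the carrier in waveform mode.
#' @param with_carrier If TRUE, multiply the envelope of each tone by a
#'   `carrier_hz` sinusoid.
#' @param carrier_hz Carrier frequency (required when `with_carrier`).
#' @param ramp_ms Rise/fall time (default 5 ms).
#' @return Numeric vector of `round(duration_ms / 1000 * fs_hz)` samples in
#'   [0, 1] (envelope mode) or [-1, 1] (waveform mode).
#' @export
synth_pip_train <- function(rate_hz, duration_ms, fs_hz,
                            with_carrier = FALSE, carrier_hz = NULL,
                            ramp_ms = 5) {
  if (duration_ms <= 0) stop("duration_ms must be positive")
  if (fs_hz <= 2 * rate_hz) stop("fs_hz too low for the stream rate")
  if (with_carrier) {
    if (is.null(carrier_hz)) stop("carrier_hz required when with_carrier = TRUE")
    if (fs_hz <= 2 * carrier_hz) stop("fs_hz too low for the carrier frequency")
  }
  tm <- stream_timing(rate_hz)
  n <- round(duration_ms / 1000 * fs_hz)
  t_ms <- (seq_len(n) - 1) / fs_hz * 1000
  env <- numeric(n)
  onsets <- seq(0, duration_ms, by = tm$soa_ms)
  onsets <- onsets[onsets + tm$tone_dur_ms <= duration_ms]
  for (on in onsets) {
    u <- t_ms - on
    idx <- which(u >= 0 & u < tm$tone_dur_ms)
    if (!length(idx)) next
    g <- rep(1, length(idx))
    ui <- u[idx]
    rise <- ui < ramp_ms
    fall <- ui > tm$tone_dur_ms - ramp_ms
    g[rise] <- 0.5 * (1 - cos(pi * ui[rise] / ramp_ms))
    g[fall] <- 0.5 * (1 - cos(pi * (tm$tone_dur_ms - ui[fall]) / ramp_ms))
    env[idx] <- g
  }
  if (with_carrier) {
    env * sin(2 * pi * carrier_hz * t_ms / 1000)
  } else {
    env
  }
}

#' Synthesize the stimulus series for one trial
#'
#' Builds the 2500-ms scene series (sum of the three streams' envelopes or
#' waveforms) and the 2000-ms probe series for a single trial of a schedule.
#'
#' @param trial One row of a `trial_schedule` (data frame with the schedule
#'   columns).
#' @param fs_hz Sampling rate.
#' @param with_carrier Envelope (default) or carrier-waveform mode.
#' @return List with `scene` (round(2.5 * fs) samples) and `probe`
#'   (round(2.0 * fs) samples).
#' @export
synth_trial_stimulus <- function(trial, fs_hz, with_carrier = FALSE) {
  rates <- c(3, 7, 19)
  carriers <- c(trial$carrier_3, trial$carrier_7, trial$carrier_19)
  scene <- Reduce(`+`, lapply(seq_along(rates), function(i) {
    synth_pip_train(rates[i], 2500, fs_hz, with_carrier = with_carrier,
                    carrier_hz = carriers[i])
  }))
  probe <- synth_pip_train(trial$probe_rate, 2000, fs_hz,
                           with_carrier = with_carrier,
                           carrier_hz = trial$probe_carrier)
  list(scene = scene, probe = probe)
}
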
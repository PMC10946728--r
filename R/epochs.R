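# Epoched multi-channel time-series container.
#
# An `epoch_set` holds a trials x channels x time numeric array together with
# the sampling metadata the analysis stages need: sampling rate, epoch start
# time, channel and trial identifiers, and the half-open stage windows
# (prestimulus, encoding, maintenance, probe) in ms relative to scene onset.

#' Construct an epoch set
#'
#' @param data Numeric array, trials x channels x time.
#' @param fs_hz Sampling rate in Hz.
#' @param t0_ms Time (ms) of the first sample relative to scene onset
#'   (default -1000).
#' @param channel_ids Character vector, one per channel.
#' @param trial_ids Integer vector, one per trial.
#' @param stages Named list of `c(start, end)` ms windows; defaults to the
#'   task stages: prestim [-1000, 0), encoding [0, 2500), maintenance
#'   [2500, 4500), probe [4500, 6000).
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, fs_hz, t0_ms = -1000,
                      channel_ids = NULL, trial_ids = NULL,
                      stages = default_stages()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  d <- dim(data)
  if (is.null(channel_ids)) channel_ids <- sprintf("MEG%03d", seq_len(d[2]))
  if (is.null(trial_ids)) trial_ids <- seq_len(d[1])
  stopifnot(length(channel_ids) == d[2], length(trial_ids) == d[1])
  structure(list(data = data, fs_hz = fs_hz, t0_ms = t0_ms,
                 channel_ids = channel_ids, trial_ids = trial_ids,
                 stages = stages),
            class = "epoch_set")
}

#' Default stage windows (ms, half-open)
#' @export
default_stages <- function() {
  list(prestim = c(-1000, 0), encoding = c(0, 2500),
       maintenance = c(2500, 4500), probe = c(4500, 6000))
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples @ %g Hz, t0 = %g ms\n",
              d[1], d[2], d[3], x$fs_hz, x$t0_ms))
  cat("Stages:", paste(sprintf("%s [%g, %g)", names(x$stages),
                               vapply(x$stages, `[`, 0, 1),
                               vapply(x$stages, `[`, 0, 2)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Number of trials / channels / samples of an epoch set
#' @param epochs An `epoch_set`.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(epochs) dim(epochs$data)[2]

#' Subset trials of an epoch set
#'
#' @param epochs An `epoch_set`.
#' @param idx Trial indices (positions, not ids) to keep.
#' @return A new `epoch_set`.
#' @export
subset_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$fs_hz, epochs$t0_ms,
            epochs$channel_ids, epochs$trial_ids[idx], epochs$stages)
}

#' Sample indices of a stage or time window
#'
#' @param epochs An `epoch_set`.
#' @param stage Stage name (one of `names(epochs$stages)`) or a numeric
#'   `c(start, end)` window in ms.
#' @return Integer sample indices into the time axis.
#' @export
stage_indices <- function(epochs, stage) {
  win <- if (is.character(stage)) {
    if (is.null(epochs$stages[[stage]])) stop("unknown stage: ", stage)
    epochs$stages[[stage]]
  } else stage
  n <- dim(epochs$data)[3]
  idx <- window_indices(epochs$t0_ms, epochs$fs_hz, n, win[1], win[2])
  if (!length(idx)) stop("window [", win[1], ", ", win[2], ") is outside the epoch")
  idx
}

# Required fields for serialization.
.epoch_fields <- c("data", "fs_hz", "t0_ms", "channel_ids", "trial_ids", "stages")

#' Write / read the epoch container
#'
#' Epochs are persisted as a single-file container (serialized R list with a
#' fixed schema). `read_epochs` validates the schema and names any missing
#' attribute.
#'
#' @param epochs An `epoch_set`.
#' @param path File path (conventionally `.epo.rds`).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(unclass(epochs)[.epoch_fields], path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read epoch container '", path, "': ", conditionMessage(e)))
  missing <- setdiff(.epoch_fields, names(obj))
  if (length(missing))
    stop("epoch container schema mismatch: missing attribute(s) ",
         paste(missing, collapse = ", "))
  epoch_set(obj$data, obj$fs_hz, obj$t0_ms, obj$channel_ids, obj$trial_ids,
            obj$stages)
}
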
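# Event-related field analysis: condition averages, global RMS time course,
# participant-level bootstrap sign-consistency inference, and stage-wise
# spatial cluster tests.

#' Average epochs into an event-related field
#'
#' @param epochs An `epoch_set`.
#' @return channels x time matrix (arithmetic mean over trials).
#' @export
erf_average <- function(epochs) {
  if (n_trials(epochs) < 1) stop("no trials")
  colMeans(epochs$data, dims = 1)
}

#' Global RMS time course
#'
#' Root mean square over channels at each time point: a global instantaneous
#' power summary of an ERF.
#'
#' @param erf channels x time matrix (or a vector for a single channel).
#' @return Numeric time series.
#' @export
rms_timecourse <- function(erf) {
  if (is.null(dim(erf))) return(abs(erf))
  sqrt(colMeans(erf^2))
}

#' Participant bootstrap sign-consistency test
#'
#' Resamples participants with replacement `n_iter` times; each iteration
#' computes the across-participant mean difference at every time point. A
#' time point is significant when the fraction of iterations whose mean lies
#' on one side of zero (strictly positive or strictly negative; exact zeros
#' count toward neither) reaches `criterion`.
#'
#' @param diffs Participants x time matrix of per-participant condition
#'   differences (e.g. RMS correct - RMS incorrect).
#' @param n_iter Bootstrap iterations (study value 10,000).
#' @param criterion Consistency criterion (study value 0.95).
#' @param seed RNG seed.
#' @param chunk Iterations per internal block (memory control).
#' @return An `rms_bootstrap`: `frac_pos`, `frac_neg`, `consistency`
#'   (= pmax of the two), `mask`, `n_iter`, `criterion`, `mean_diff`.
#' @export
bootstrap_sign_consistency <- function(diffs, n_iter = 10000,
                                       criterion = 0.95, seed = NULL,
                                       chunk = 1000) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 2) stop("need at least 2 participants")
  local_rng(seed)
  nt <- ncol(diffs)
  pos <- neg <- numeric(nt)
  done <- 0
  while (done < n_iter) {
    b <- min(chunk, n_iter - done)
    counts <- stats::rmultinom(b, n, rep(1 / n, n))     # n x b resample counts
    means <- crossprod(counts, diffs) / n               # b x nt
    pos <- pos + colSums(means > 0)
    neg <- neg + colSums(means < 0)
    done <- done + b
  }
  frac_pos <- pos / n_iter
  frac_neg <- neg / n_iter
  consistency <- pmax(frac_pos, frac_neg)
  structure(list(frac_pos = frac_pos, frac_neg = frac_neg,
                 consistency = consistency,
                 mask = consistency >= criterion,
                 n_iter = n_iter, criterion = criterion,
                 mean_diff = colMeans(diffs)),
            class = "rms_bootstrap")
}

#' @export
print.rms_bootstrap <- function(x, ...) {
  cat(sprintf("RMS bootstrap: %d iterations, criterion %.2f, %d/%d time points significant\n",
              x$n_iter, x$criterion, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Exhaustive enumeration oracle for the sign-consistency bootstrap
#'
#' Enumerates all n^n ordered resamples (feasible for n <= 6) and returns the
#' exact directional fractions at each time point. Used to validate the
#' Monte-Carlo bootstrap on small inputs.
#'
#' @param diffs Participants x time matrix.
#' @return List with exact `frac_pos`, `frac_neg`.
#' @export
enumerate_sign_consistency <- function(diffs) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n > 6) stop("enumeration is limited to n <= 6 participants")
  grids <- rep(list(seq_len(n)), n)
  combos <- as.matrix(expand.grid(grids))
  nt <- ncol(diffs)
  pos <- neg <- numeric(nt)
  for (r in seq_len(nrow(combos))) {
    m <- colMeans(diffs[combos[r, ], , drop = FALSE])
    pos <- pos + (m > 0)
    neg <- neg + (m < 0)
  }
  list(frac_pos = pos / nrow(combos), frac_neg = neg / nrow(combos))
}

#' Stage-wise spatial cluster test on ERFs
#'
#' Averages each participant's per-condition ERF over a stage's time window
#' to one value per channel, then runs the spatial-only cluster permutation
#' test on the resulting channel maps.
#'
#' @param correct,incorrect Participants x channels x time arrays of
#'   per-participant ERFs (same order of participants).
#' @param stage Stage name or `c(start, end)` ms window.
#' @param array A `sensor_array` (for adjacency).
#' @param t0_ms,fs_hz Time axis of the ERF arrays.
#' @param stages Stage window lookup (default [default_stages()]).
#' @param ... Passed to [permutation_cluster_test()].
#' @return A `cluster_result`.
#' @export
erf_stage_cluster_test <- function(correct, incorrect, stage, array,
                                   t0_ms = -1000, fs_hz,
                                   stages = default_stages(), ...) {
  stopifnot(identical(dim(correct), dim(incorrect)))
  win <- if (is.character(stage)) stages[[stage]] else stage
  idx <- window_indices(t0_ms, fs_hz, dim(correct)[3], win[1], win[2])
  a <- apply(correct[, , idx, drop = FALSE], c(1, 2), mean)
  b <- apply(incorrect[, , idx, drop = FALSE], c(1, 2), mean)
  permutation_cluster_test(a, b, array$adjacency, ...)
}
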
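# Trial-level cleaning and conditioning.
#
# Fixed pipeline order: power-based outlier rejection -> DSS denoising ->
# baseline correction -> accuracy split -> RT-ordered trial-count equating.

#' Reject trials with outlying broadband power
#'
#' Per-trial power is the mean of squared values over all channels and time
#' points; trials whose power deviates from the across-trial mean by more
#' than `z_thresh` standard deviations are discarded.
#'
#' @param epochs An `epoch_set` with >= 3 trials.
#' @param z_thresh SD multiplier (study value 2).
#' @return List with `epochs` (retained trials) and `rejected` (trial ids).
#' @export
reject_outlier_trials <- function(epochs, z_thresh = 2) {
  if (n_trials(epochs) < 3) stop("need at least 3 trials")
  pw <- apply(epochs$data, 1, function(x) mean(x^2))
  s <- stats::sd(pw)
  if (!is.finite(s) || s == 0) {
    keep <- seq_along(pw)
  } else {
    keep <- which(abs(pw - mean(pw)) <= z_thresh * s)
  }
  if (!length(keep)) stop("all trials rejected as outliers")
  list(epochs = subset_trials(epochs, keep),
       rejected = epochs$trial_ids[setdiff(seq_along(pw), keep)])
}

#' Fit a DSS (denoising source separation) model
#'
#' Evoked-bias DSS: finds spatial components ordered by trial-to-trial
#' reproducibility. With C0 the channel covariance of the single-trial data
#' and C1 the channel covariance of the trial average (both over the bias
#' window), the model solves the generalized symmetric eigenproblem
#' C1 v = lambda C0 v by whitening with C0 (eigenvalues below
#' `rank_tol` x the largest are truncated) and eigendecomposing the whitened
#' C1. Scores are the bias ratios lambda, sorted descending; the first
#' components are the "most reproducible" ones. Non-reproducible artifacts
#' (drift, line noise) concentrate in low-score components.
#'
#' @param epochs An `epoch_set` with >= 2 trials.
#' @param bias_window Stage name or `c(start, end)` ms window used to compute
#'   both covariances (default the encoding stage, 0-2500 ms).
#' @param rank_tol Relative eigenvalue cutoff for C0 whitening.
#' @return A `dss_model`: `filters` (channels x components), `patterns`
#'   (components x channels), `scores`, `rank`.
#' @export
dss_decompose <- function(epochs, bias_window = "encoding", rank_tol = 1e-9) {
  nt <- n_trials(epochs)
  if (nt < 2) stop("DSS needs at least 2 trials")
  idx <- stage_indices(epochs, bias_window)
  nch <- n_channels(epochs)
  if (nch > length(idx) * nt)
    stop("more channels than samples x trials in the bias window")
  ns <- length(idx)

  C0 <- matrix(0, nch, nch)
  xbar <- matrix(0, nch, ns)
  for (i in seq_len(nt)) {
    x <- epochs$data[i, , idx]
    x <- x - rowMeans(x)
    C0 <- C0 + tcrossprod(x) / ns
    xbar <- xbar + x
  }
  C0 <- C0 / nt
  xbar <- xbar / nt
  C1 <- tcrossprod(xbar) / ns

  e0 <- eigen(C0, symmetric = TRUE)
  keep <- which(e0$values > rank_tol * max(e0$values))
  if (length(keep) < 2)
    stop("C0 is rank deficient beyond truncation (retained rank ",
         length(keep), " of ", nch, "); data may be constant or degenerate")
  U <- e0$vectors[, keep, drop = FALSE]
  d <- e0$values[keep]
  W <- U %*% diag(1 / sqrt(d), length(d))          # whitening, channels x r
  C1w <- crossprod(W, C1 %*% W)
  e1 <- eigen((C1w + t(C1w)) / 2, symmetric = TRUE)
  V <- e1$vectors
  scores <- pmax(e1$values, 0)
  filters <- W %*% V                               # channels x r
  patterns <- crossprod(V, diag(sqrt(d), length(d)) %*% t(U))  # r x channels
  structure(list(filters = filters, patterns = patterns, scores = scores,
                 rank = length(d), bias_window = bias_window),
            class = "dss_model")
}

#' @export
print.dss_model <- function(x, ...) {
  cat(sprintf("DSS model: rank %d, top scores %s\n", x$rank,
              paste(signif(utils::head(x$scores, 5), 3), collapse = ", ")))
  invisible(x)
}

#' Project epochs onto leading DSS components
#'
#' Projects each trial onto the first `keep` components and back into sensor
#' space. Output has the same shape as the input; with `keep` equal to the
#' model rank the operation is an identity on the retained subspace.
#'
#' @param epochs An `epoch_set`.
#' @param model A `dss_model` from [dss_decompose()].
#' @param keep Number of leading components to retain.
#' @return A denoised `epoch_set`.
#' @export
dss_denoise <- function(epochs, model, keep) {
  if (keep < 1 || keep > model$rank) stop("keep must be in 1..rank")
  Fk <- model$filters[, seq_len(keep), drop = FALSE]
  Pk <- model$patterns[seq_len(keep), , drop = FALSE]
  proj <- crossprod(Pk, t(Fk))      # t(Pk) %*% t(Fk): channels x channels
  dat <- epochs$data
  for (i in seq_len(dim(dat)[1])) {
    dat[i, , ] <- proj %*% dat[i, , ]
  }
  epoch_set(dat, epochs$fs_hz, epochs$t0_ms, epochs$channel_ids,
            epochs$trial_ids, epochs$stages)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window.
#'
#' @param epochs An `epoch_set`.
#' @param window_ms Baseline window (default the 500-ms prestimulus interval
#'   `c(-500, 0)`).
#' @return A baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-500, 0)) {
  idx <- stage_indices(epochs, window_ms)
  dat <- epochs$data
  bl <- apply(dat[, , idx, drop = FALSE], c(1, 2), mean)
  dat <- dat - as.vector(bl)   # recycles trials x channels over time (dim 3)
  epoch_set(dat, epochs$fs_hz, epochs$t0_ms, epochs$channel_ids,
            epochs$trial_ids, epochs$stages)
}

#' Equate correct/incorrect trial counts by response time
#'
#' Retains, from the correct trials, the `n_incorrect` fastest responses
#' (ties broken by trial index), discarding the slow tail so both conditions
#' contribute the same number of trials to averaging.
#'
#' @param correct_epochs `epoch_set` of correct trials.
#' @param incorrect_epochs `epoch_set` of incorrect trials (only its trial
#'   count is used); alternatively pass the count via `n_incorrect`.
#' @param rt_ms Response time (ms) of each correct trial, aligned with
#'   `correct_epochs` trial order.
#' @param n_incorrect Optional explicit count, overriding `incorrect_epochs`.
#' @return `epoch_set` of the retained correct trials.
#' @export
equate_trial_counts <- function(correct_epochs, incorrect_epochs = NULL,
                                rt_ms, n_incorrect = NULL) {
  if (is.null(n_incorrect)) n_incorrect <- n_trials(incorrect_epochs)
  nc <- n_trials(correct_epochs)
  if (length(rt_ms) != nc) stop("rt_ms must have one entry per correct trial")
  if (n_incorrect < 1) stop("need at least one incorrect trial")
  if (nc < n_incorrect)
    stop("fewer correct (", nc, ") than incorrect (", n_incorrect, ") trials")
  ord <- order(rt_ms, seq_len(nc))
  keep <- sort(ord[seq_len(n_incorrect)])
  subset_trials(correct_epochs, keep)
}

#' Run the full preprocessing pipeline for one participant
#'
#' Applies, in order: power-based trial rejection, evoked-bias DSS cleaning
#' (keeping the top `cleanup_keep_frac` of the rank), baseline correction,
#' the RT outlier filter, the accuracy split (correct = TP/TN) and RT-based
#' trial-count equating.
#'
#' @param epochs An `epoch_set`.
#' @param behavior Behaviour data frame aligned with the epochs (columns
#'   `outcome`, `rt_ms`).
#' @param z_thresh Trial-power rejection threshold (SDs).
#' @param cleanup_keep_frac Fraction of DSS components kept at cleaning.
#' @param rt_k RT outlier threshold (SDs).
#' @param baseline_window_ms Baseline window.
#' @return List: `correct`, `incorrect` (`epoch_set`s with equal trial
#'   counts), `behavior` (filtered), `rt_correct` (RTs of retained correct
#'   trials), `dss` (model), `report` (stage-by-stage counts).
#' @export
preprocess_participant <- function(epochs, behavior, z_thresh = 2,
                                   cleanup_keep_frac = 0.8, rt_k = 2.5,
                                   baseline_window_ms = c(-500, 0)) {
  stopifnot(nrow(behavior) == n_trials(epochs))
  rej <- reject_outlier_trials(epochs, z_thresh)
  keep_pos <- match(rej$epochs$trial_ids, epochs$trial_ids)
  behavior <- behavior[keep_pos, , drop = FALSE]

  model <- dss_decompose(rej$epochs, "encoding")
  keep_n <- max(2L, ceiling(model$rank * cleanup_keep_frac))
  clean <- dss_denoise(rej$epochs, model, keep_n)
  clean <- baseline_correct(clean, baseline_window_ms)

  behavior$condition <- ifelse(behavior$outcome %in% c("TP", "TN"),
                               "correct", "incorrect")
  filt <- filter_rt_outliers(behavior, k = rt_k)
  keep_pos2 <- match(filt$trial_index, behavior$trial_index)
  clean <- subset_trials(clean, keep_pos2)

  is_cor <- filt$condition == "correct"
  if (!any(!is_cor)) stop("no incorrect trials; cannot equate conditions")
  correct <- subset_trials(clean, which(is_cor))
  incorrect <- subset_trials(clean, which(!is_cor))
  rt_cor <- filt$rt_ms[is_cor]
  eq <- equate_trial_counts(correct, incorrect, rt_ms = rt_cor)
  rt_keep <- sort(order(rt_cor, seq_along(rt_cor))[seq_len(n_trials(incorrect))])

  report <- list(n_input = n_trials(epochs),
                 rejected_trials = rej$rejected,
                 dss_rank = model$rank, dss_keep = keep_n,
                 dss_scores = model$scores,
                 n_rt_filtered = nrow(behavior) - nrow(filt),
                 n_correct = n_trials(correct),
                 n_incorrect = n_trials(incorrect),
                 n_equated = n_trials(eq))
  list(correct = eq, incorrect = incorrect, behavior = filt,
       rt_correct = rt_cor[rt_keep], dss = model, report = report)
}
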
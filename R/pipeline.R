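# End-to-end orchestration: configuration, seeded simulate -> preprocess ->
# behaviour / ERF / TFR / PSD runs, and report generation.

#' Default run configuration
#'
#' All analysis parameters with defaults mirroring the study design (600 Hz,
#' 274 channels, 336 trials, 23 participants, 10,000 bootstrap iterations,
#' 1000 permutations, minimum 3 channels per cluster, 2-SD trial filter,
#' 2.5-SD RT filter). The `"reduced"` preset scales the simulation down
#' (8 participants, 64 channels, 150 Hz, 60 trials, 2000 bootstrap
#' iterations, 200 permutations) for fast exploratory runs and testing.
#'
#' @param scale `"full"` or `"reduced"`.
#' @param seed Master seed.
#' @param effects `"default"` (condition effects planted) or `"null"` (all
#'   condition amplitudes equalized).
#' @return Named list of parameters (a `run_config`).
#' @export
default_config <- function(scale = c("reduced", "full"), seed = 1L,
                           effects = c("default", "null")) {
  scale <- match.arg(scale)
  effects <- match.arg(effects)
  full <- scale == "full"
  cfg <- list(
    scale = scale, seed = as.integer(seed), effects = effects,
    n_participants = if (full) 23L else 8L,
    n_per_cell = if (full) 56L else 10L,
    n_channels = if (full) 274L else 64L,
    fs_hz = if (full) 600 else 150,
    n_boot = if (full) 10000L else 2000L,
    n_perm = if (full) 1000L else 200L,
    min_channels = 3L, alpha_cf = 0.05,
    z_thresh = 2, rt_k = 2.5, rt_cells = "outcome",
    cleanup_keep_frac = 0.8, dss_keep_psd = 2L,
    baseline_ms = c(-500, 0),
    boot_criterion = 0.95,
    tfr_window_ms = 400, tfr_step_ms = 50,
    tfr_fmin = 1, tfr_fmax = 30, tfr_fstep = 0.5,
    tfr_baseline_ms = c(-400, -200),
    bands = canonical_bands(),
    tfr_stages = c("prestim", "encoding", "maintenance"),
    psd_f_range = c(1, 21), psd_k = 10L,
    participant_sd = 0.15
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Write / read a run configuration (YAML)
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- default_config()
  missing <- setdiff(names(ref), names(cfg))
  if (length(missing))
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  cfg$bands <- lapply(cfg$bands, as.numeric)
  class(cfg) <- c("run_config", "list")
  cfg
}

# Simulation parameter set implied by a config.
config_sim_params <- function(config, array) {
  eff <- default_effects(array)
  if (config$effects == "null") eff <- null_effects(eff)
  sim_params(fs_hz = config$fs_hz, effects = eff,
             participant_sd = config$participant_sd,
             seed = config$seed)
}

#' Run the full analysis pipeline
#'
#' Simulates a study per the configuration (unless `sim_dir` points at an
#' existing simulation), preprocesses each participant, and runs the
#' behavioural, ERF, time-frequency and PSD analyses. All stage outputs and
#' a JSON summary are written under `outdir`. Deterministic given the
#' config's master seed.
#'
#' @param config A `run_config` from [default_config()] / [read_config()].
#' @param outdir Output directory.
#' @param sim_dir Optional existing simulation directory with a
#'   `manifest.csv` (from [simulate_study()]).
#' @param verbose Print stage progress.
#' @return (Invisibly) the summary list.
#' @export
run_pipeline <- function(config, outdir = tempfile("astmeg_run"),
                         sim_dir = NULL, verbose = TRUE) {
  t_start <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  array <- make_sensor_array(config$n_channels,
                             seed = derive_seed(config$seed, "array"))
  params <- config_sim_params(config, array)

  if (is.null(sim_dir)) {
    say("Simulating %d participants (%s scale)...", config$n_participants,
        config$scale)
    sim_dir <- file.path(outdir, "sim")
    manifest <- simulate_study(config$n_participants, array, params,
                               n_per_cell = config$n_per_cell,
                               seed = config$seed, outdir = sim_dir)
  } else {
    manifest <- utils::read.csv(file.path(sim_dir, "manifest.csv"),
                                stringsAsFactors = FALSE)
  }

  np <- nrow(manifest)
  behavior_all <- vector("list", np)
  erf_c <- erf_i <- NULL
  rms_diff <- NULL
  tfr_c <- tfr_i <- vector("list", np)
  psd_peaks <- vector("list", np)
  psd_maint_snr <- matrix(0, np, 3)
  psd_enc_snr <- matrix(0, np, 3)
  reports <- vector("list", np)

  for (p in seq_len(np)) {
    say("Preprocessing and analysing participant %d/%d...", p, np)
    epochs <- read_epochs(manifest$epochs[p])
    behavior <- utils::read.csv(manifest$behavior[p], stringsAsFactors = FALSE)
    prep <- preprocess_participant(epochs, behavior,
                                   z_thresh = config$z_thresh,
                                   cleanup_keep_frac = config$cleanup_keep_frac,
                                   rt_k = config$rt_k)
    behavior_all[[p]] <- behavior
    reports[[p]] <- prep$report

    ec <- erf_average(prep$correct)
    ei <- erf_average(prep$incorrect)
    if (is.null(erf_c)) {
      nt <- ncol(ec)
      erf_c <- array(0, c(np, nrow(ec), nt))
      erf_i <- array(0, c(np, nrow(ec), nt))
      rms_diff <- matrix(0, np, nt)
    }
    erf_c[p, , ] <- ec
    erf_i[p, , ] <- ei
    rms_diff[p, ] <- rms_timecourse(ec) - rms_timecourse(ei)

    tc <- stft_power(prep$correct, config$tfr_fmin, config$tfr_fmax,
                     config$tfr_fstep, config$tfr_window_ms, config$tfr_step_ms)
    ti <- stft_power(prep$incorrect, config$tfr_fmin, config$tfr_fmax,
                     config$tfr_fstep, config$tfr_window_ms, config$tfr_step_ms)
    tfr_c[[p]] <- baseline_normalize_tfr(tc, config$tfr_baseline_ms)
    tfr_i[[p]] <- baseline_normalize_tfr(ti, config$tfr_baseline_ms)

    psd_enc <- psd_participant(prep$correct, prep$incorrect, "encoding",
                               dss_keep = config$dss_keep_psd,
                               f_range = config$psd_f_range, k = config$psd_k)
    psd_peaks[[p]] <- psd_enc$peaks
    psd_enc_snr[p, ] <- psd_enc$snr$snr
    psd_maint <- psd_participant(prep$correct, prep$incorrect, "maintenance",
                                 dss_keep = config$dss_keep_psd,
                                 f_range = config$psd_f_range, k = config$psd_k)
    psd_maint_snr[p, ] <- psd_maint$snr$snr
  }

  say("Group statistics...")
  behavior_df <- do.call(rbind, behavior_all)
  beh <- behavior_study_stats(behavior_df, rt_k = config$rt_k,
                              cells = config$rt_cells)

  boot <- bootstrap_sign_consistency(rms_diff, n_iter = config$n_boot,
                                     criterion = config$boot_criterion,
                                     seed = derive_seed(config$seed, "boot"))
  fs <- config$fs_hz
  erf_clusters <- list(
    encoding = erf_stage_cluster_test(erf_c, erf_i, "encoding", array,
                                      t0_ms = -1000, fs_hz = fs,
                                      n_perm = config$n_perm,
                                      min_channels = config$min_channels,
                                      alpha_cf = config$alpha_cf,
                                      seed = derive_seed(config$seed, "erfclu", 1)),
    maintenance = erf_stage_cluster_test(erf_c, erf_i, "maintenance", array,
                                         t0_ms = -1000, fs_hz = fs,
                                         n_perm = config$n_perm,
                                         min_channels = config$min_channels,
                                         alpha_cf = config$alpha_cf,
                                         seed = derive_seed(config$seed, "erfclu", 2))
  )

  tfr_clusters <- list()
  k <- 0
  for (band_name in names(config$bands)) {
    for (stage in config$tfr_stages) {
      k <- k + 1
      tfr_clusters[[paste(band_name, stage, sep = "_")]] <-
        tfr_stage_cluster_test(tfr_c, tfr_i, config$bands[[band_name]], stage,
                               array, n_perm = config$n_perm,
                               min_channels = config$min_channels,
                               alpha_cf = config$alpha_cf,
                               seed = derive_seed(config$seed, "tfrclu", k))
    }
  }

  psd_anova <- psd_peak_anova(psd_peaks)

  summary <- list(
    config = unclass(config),
    behavior = list(
      accuracy = mean(behavior_df$outcome %in% c("TP", "TN")),
      anova_pct = beh$anova_pct$table,
      anova_rt = beh$anova_rt$table,
      followup_rt = beh$followup_rt
    ),
    preprocessing = lapply(reports, function(r)
      r[c("n_input", "dss_rank", "dss_keep", "n_correct", "n_incorrect",
          "n_equated")]),
    erf = list(
      bootstrap = list(n_iter = boot$n_iter, criterion = boot$criterion,
                       n_significant = sum(boot$mask),
                       n_timepoints = length(boot$mask)),
      clusters = lapply(erf_clusters, summarize_clusters)
    ),
    tfr = lapply(tfr_clusters, summarize_clusters),
    psd = list(
      anova = psd_anova$table,
      encoding_peaks = Reduce(`+`, lapply(psd_peaks, function(x)
        as.matrix(x[, c("correct", "incorrect")]))) / np,
      encoding_snr = stats::setNames(colMeans(psd_enc_snr), c("3", "7", "19")),
      maintenance_snr = stats::setNames(colMeans(psd_maint_snr),
                                        c("3", "7", "19")),
      maintenance_max_peak = max(colMeans(psd_maint_snr))
    ),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  utils::write.csv(behavior_df, file.path(outdir, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(beh$table, file.path(outdir, "behavior_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(time_ms = epoch_times(-1000, fs, ncol(rms_diff)),
                              mean_diff = boot$mean_diff,
                              consistency = boot$consistency,
                              significant = boot$mask),
                   file.path(outdir, "rms_bootstrap.csv"), row.names = FALSE)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  say("Done in %.1f s; outputs in %s", summary$elapsed_s, outdir)
  # full result objects for programmatic consumers (not serialized)
  summary$results <- list(erf_clusters = erf_clusters,
                          tfr_clusters = tfr_clusters,
                          bootstrap = boot, behavior = beh,
                          psd_peaks = psd_peaks,
                          psd_enc_snr = psd_enc_snr,
                          psd_maint_snr = psd_maint_snr,
                          array = array)
  invisible(summary)
}

# Compact JSON-friendly cluster summary.
summarize_clusters <- function(result) {
  list(n_clusters = length(result$clusters),
       threshold = result$threshold,
       n_perm = result$n_perm,
       clusters = lapply(result$clusters, function(cl) {
         out <- list(n_channels = length(cl$channels), stat = cl$stat,
                     sign = cl$sign, p = cl$p)
         if (!is.null(result$times_ms)) {
           sp <- cluster_time_span(cl, result)
           out$time_span_ms <- sp
         }
         out
       }))
}
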
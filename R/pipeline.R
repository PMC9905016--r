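# End-to-end orchestration: simulate -> preprocess -> marginalize -> cvPCA
# -> decode -> encode -> subspace/timing, from a single config.

#' Default pipeline configuration
#'
#' Returns the nested parameter list consumed by [run_pipeline()]. The
#' `session` block mirrors the emulated experiment (12 videos x 12 sounds x
#' 4 repeats, 4 s movies with 2 s gaps, 40 Hz face camera, 100 Hz eye
#' camera, 30 ms behavioral lead); the `analysis` block holds the standard
#' processing parameters (30 ms bins, 43 ms causal smoothing, (-1, 3.8) s
#' window, 4 sound / 30 video PCs, 1,000 shuffles, ridge penalty grid,
#' -90..+240 ms encoding lags, rank-40 movement subspace). Every field can
#' be overridden, and the whole list can be round-tripped through YAML with
#' [read_config()] / [write_config()].
#'
#' @param ... named overrides, e.g. `session = list(n_neurons = 30)`
#'   (merged recursively into the defaults).
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    session = list(
      n_videos = 12, n_sounds = 12, n_repeats = 4,
      n_neurons = 80, n_motion_pcs = 128,
      sound_rank = 1, kernel_amp = 4, lead_time = 0.030,
      trial_duration = 4, inter_trial_interval = 2,
      spontaneous_duration = 600,
      camera_rate = 40, eye_rate = 100
    ),
    analysis = list(
      bin_size = 0.030, smoothing_sigma = 0.043, window = c(-1, 3.8),
      n_sound_pcs = 4, n_video_pcs = 30,
      n_shuffles = 1000, shuffle_percentile = 99,
      lambda_grid = 10^seq(-3, 5), lags = -3:8,
      rrr_rank = 40, n_rrr_lags = 21, overlap_k = 4, n_random = 200,
      max_lag = 2
    )
  )
  utils::modifyList(cfg, list(...))
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname default_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Generates a session from the config, preprocesses it into neural and
#' behavioral trial tensors, and runs every analysis stage: factorial
#' marginalization, cvPCA spectra with the shuffle dimensionality test,
#' template decoding of sound and video identity from neural and behavioral
#' data, the three ridge encoding models (auditory / behavioral / full) with
#' trial-average and trial-to-trial evaluation, the reduced-rank-regression
#' movement subspace with its overlap against the sound subspace, and the
#' two movement-to-neural timing measures. All stochastic stages derive
#' their seeds from `seed`, so a rerun with the same config and seed is
#' identical.
#'
#' @param config a [default_config()]-style list.
#' @param seed integer master seed.
#' @param verbose print stage progress.
#' @return object of class `pipeline_report`: a named list of stage
#'   results plus a `summary` list of headline numbers.
#' @export
run_pipeline <- function(config = default_config(), seed = 1, verbose = FALSE) {
  sc <- config$session
  an <- config$analysis
  seeds <- child_seeds(seed, 6)
  say <- function(...) if (verbose) message(...)

  say("simulate")
  schedule <- generate_schedule(sc$n_videos, sc$n_sounds, sc$n_repeats,
                                trial_duration = sc$trial_duration,
                                inter_trial_interval = sc$inter_trial_interval,
                                spontaneous_duration = sc$spontaneous_duration,
                                seed = seeds[[1]])
  truth <- make_ground_truth(n_neurons = sc$n_neurons,
                             n_motion_pcs = sc$n_motion_pcs,
                             n_sounds = sc$n_sounds, n_videos = sc$n_videos,
                             sound_rank = sc$sound_rank,
                             kernel_amp = sc$kernel_amp,
                             lead_time = sc$lead_time,
                             seed = seeds[[2]])
  session <- generate_session(schedule, truth, camera_rate = sc$camera_rate,
                              eye_rate = sc$eye_rate, seed = seeds[[3]])

  say("preprocess")
  tensors <- session_tensors(session, bin_size = an$bin_size,
                             sigma = an$smoothing_sigma, window = an$window)
  split <- repeat_split(sc$n_repeats)

  say("marginalize")
  marg <- marginalize(tensors$neural)
  marg_tr <- marginalize(tensors$neural[, , , split$train, , drop = FALSE])
  marg_te <- marginalize(tensors$neural[, , , split$test, , drop = FALSE])

  say("cvpca")
  cv_sound <- cvpca_spectrum(marg_tr$A, marg_te$A)
  cv_video <- cvpca_spectrum(marg_tr$V, marg_te$V)
  sh_sound <- shuffle_significance(tensors$neural, "sound",
                                   n_shuffles = an$n_shuffles,
                                   percentile = an$shuffle_percentile,
                                   seed = seeds[[4]])
  sh_inter <- shuffle_significance(tensors$neural, "interaction",
                                   n_shuffles = an$n_shuffles,
                                   percentile = an$shuffle_percentile,
                                   seed = seeds[[4]])
  # total-variance shares (video + sound + interaction normalization)
  cv_inter <- cvpca_spectrum(marg_tr$I, marg_te$I)
  tot <- sum(cv_sound$vhat) + sum(cv_video$vhat) + sum(cv_inter$vhat)

  say("decode")
  dec_sound <- template_decode(tensors$neural, "sound", split, an$n_sound_pcs)
  dec_video <- template_decode(tensors$neural, "video", split,
                               min(an$n_video_pcs, sc$n_neurons))
  dec_beh <- behavioral_decode(tensors$behavioral, "sound", split,
                               an$n_sound_pcs)

  say("encode")
  W_full <- component_pcs(marg, "sound")
  Y <- project_target(tensors$neural, marg, W_full, an$n_sound_pcs,
                      pad = length(an$lags))
  bmarg <- marginalize(tensors$behavioral)
  # the padded designs are large at full session scale; build, fit and
  # evaluate one model at a time so only one design matrix is ever alive
  kinds <- c("auditory", "behavioral", "full")
  fits <- list()
  enc_avg <- enc_noise <- stats::setNames(numeric(3), kinds)
  for (k in kinds) {
    des <- build_design(k, tensors$neural,
                        behavior = if (k == "auditory") NULL else
                          tensors$behavioral,
                        behavior_marg = bmarg, lags = an$lags)
    fit <- fit_ridge(des, Y, lambda_grid = an$lambda_grid, split = split)
    enc_avg[k] <- evaluate_trial_average(fit, des, Y, split)
    enc_noise[k] <- evaluate_noise_correlation(fit, des, Y, split)
    fits[[k]] <- fit
    rm(des)
    gc(FALSE)
  }

  say("subspace")
  ep <- schedule$spontaneous_epoch
  msel <- session$motion$times >= ep[1] & session$motion$times <= ep[2]
  mot <- zscore_columns(session$motion$pcs[msel, , drop = FALSE])
  nb <- bin_and_zscore(session$spikes, sc$n_neurons, 1 / sc$camera_rate,
                       sigma = NULL, t_start = 0, t_end = session$duration,
                       zscore = FALSE)
  bsel <- nb$times >= ep[1] & nb$times <= ep[2]
  S <- zscore_columns(nb$traces[bsel, , drop = FALSE])
  npts <- min(nrow(S), nrow(mot))
  lag_des <- build_lagged_motion(mot[seq_len(npts), , drop = FALSE],
                                 an$n_rrr_lags)
  rrr <- fit_rrr(lag_des$values, S[lag_des$rows, , drop = FALSE],
                 rank = min(an$rrr_rank, sc$n_neurons, ncol(lag_des$values)))
  overlap <- subspace_overlap(marg_tr$A, marg_te$A, rrr$C, k = an$overlap_k,
                              auditory_vhat = cv_sound,
                              n_random = an$n_random, seed = seeds[[5]])
  timing <- spontaneous_timing(session, W_full[, 1],
                               n_lags = an$n_rrr_lags, max_lag = an$max_lag)

  summary <- list(
    n_trials = nrow(schedule$trials),
    sound_dimensionality = sh_sound$n_significant,
    interaction_dimensionality = sh_inter$n_significant,
    sound_pc1_share = cv_sound$vhat[1] / sum(cv_sound$vhat),
    sound_total_share = sum(cv_sound$vhat) / tot,
    video_total_share = sum(cv_video$vhat) / tot,
    decode_sound = dec_sound$accuracy,
    decode_video = dec_video$accuracy,
    decode_sound_behavior = dec_beh$accuracy,
    encoding_trial_average = enc_avg,
    encoding_noise = enc_noise,
    overlap_ratio = overlap$overlap_ratio,
    overlap_threshold = overlap$random_threshold,
    xcorr_lag_ms = 1000 * timing$xcorr_lag_s,
    weight_delay_ms = 1000 * timing$weight_delay_s
  )
  structure(list(config = config, seed = seed,
                 schedule = schedule, truth = truth,
                 cv_sound = cv_sound, cv_video = cv_video,
                 shuffle_sound = sh_sound, shuffle_interaction = sh_inter,
                 decode_sound = dec_sound, decode_video = dec_video,
                 decode_behavior = dec_beh,
                 encoding = list(fits = fits, trial_average = enc_avg,
                                 noise = enc_noise),
                 rrr = rrr, overlap = overlap, timing = timing,
                 summary = summary),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("Pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  %d trials; sound dimensionality %d (interaction %d)\n",
              s$n_trials, s$sound_dimensionality, s$interaction_dimensionality))
  cat(sprintf("  sound PC1 share %.0f%%; total variance: video %.1f%%, sound %.1f%%\n",
              100 * s$sound_pc1_share, 100 * s$video_total_share,
              100 * s$sound_total_share))
  cat(sprintf("  decoding: video %.0f%%, sound %.0f%%, sound-from-behavior %.0f%%\n",
              100 * s$decode_video, 100 * s$decode_sound,
              100 * s$decode_sound_behavior))
  cat(sprintf("  encoding r (trial-avg): auditory %.2f, behavioral %.2f, full %.2f\n",
              s$encoding_trial_average["auditory"],
              s$encoding_trial_average["behavioral"],
              s$encoding_trial_average["full"]))
  cat(sprintf("  subspace overlap %.0f%% (chance threshold %.0f%%)\n",
              100 * s$overlap_ratio, 100 * s$overlap_threshold))
  cat(sprintf("  timing: xcorr lag %+.0f ms, weight peak %+.0f ms\n",
              s$xcorr_lag_ms, s$weight_delay_ms))
  invisible(x)
}
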
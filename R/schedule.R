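#' Generate a factorial audiovisual stimulus schedule
#'
#' Builds the balanced factorial design used throughout the package: every
#' combination of video and sound appears exactly `n_repeats` times. One
#' randomized ordering of the `n_videos * n_sounds` pairs is drawn and the
#' same sequence is then repeated `n_repeats` times, so the repeat index of a
#' trial is the sweep it belongs to. With the default 12 videos x 12 sounds x
#' 4 repeats this yields 576 trials over 144 unique pairs. Video id
#' `n_videos` denotes the blank (gray) screen and sound id `n_sounds`
#' denotes silence.
#'
#' Trials last `trial_duration` seconds and are separated by
#' `inter_trial_interval` seconds. A stimulus-free spontaneous epoch of
#' `spontaneous_duration` seconds is placed after the last trial; it is used
#' downstream to estimate the movement-related neural subspace and
#' movement-to-neural timing.
#'
#' @param n_videos,n_sounds,n_repeats design counts (positive integers).
#' @param trial_duration stimulus duration in seconds.
#' @param inter_trial_interval gap between consecutive trials, seconds.
#' @param first_onset onset time of the first trial, seconds.
#' @param spontaneous_duration length of the stimulus-free epoch, seconds.
#' @param spontaneous_gap gap between the last trial offset and the start of
#'   the spontaneous epoch, seconds.
#' @param seed integer seed for the trial-order permutation; the caller's RNG
#'   state is left untouched.
#' @return An object of class `stim_schedule`: a list with `trials` (a
#'   data.frame with columns `onset`, `video_id`, `sound_id`, `rep`),
#'   design counts, timing parameters and `spontaneous_epoch` (start, end).
#' @examples
#' sched <- generate_schedule(3, 2, 2, seed = 1)
#' nrow(sched$trials)  # 12
#' @export
generate_schedule <- function(n_videos = 12, n_sounds = 12, n_repeats = 4,
                              trial_duration = 4, inter_trial_interval = 2,
                              first_onset = 10, spontaneous_duration = 600,
                              spontaneous_gap = 10, seed = NULL) {
  counts <- c(n_videos, n_sounds, n_repeats)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop_arg("n_videos, n_sounds and n_repeats must be positive integers")
  if (trial_duration <= 0 || inter_trial_interval < 0)
    stop_arg("invalid trial timing")

  pairs <- expand.grid(video_id = seq_len(n_videos), sound_id = seq_len(n_sounds))
  n_pairs <- nrow(pairs)
  ord <- with_seed(seed, sample.int(n_pairs))
  trials <- do.call(rbind, lapply(seq_len(n_repeats), function(r) {
    data.frame(video_id = pairs$video_id[ord], sound_id = pairs$sound_id[ord],
               rep = r)
  }))
  spacing <- trial_duration + inter_trial_interval
  trials$onset <- first_onset + (seq_len(nrow(trials)) - 1) * spacing
  trials <- trials[, c("onset", "video_id", "sound_id", "rep")]
  last_off <- trials$onset[nrow(trials)] + trial_duration
  spont <- c(last_off + spontaneous_gap,
             last_off + spontaneous_gap + spontaneous_duration)
  structure(list(
    trials = trials,
    n_videos = n_videos, n_sounds = n_sounds, n_repeats = n_repeats,
    trial_duration = trial_duration,
    inter_trial_interval = inter_trial_interval,
    spontaneous_epoch = spont,
    blank_video = n_videos, silence = n_sounds,
    seed = seed
  ), class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat("Stimulus schedule:", nrow(x$trials), "trials\n")
  cat(sprintf("  %d videos x %d sounds x %d repeats (blank video = %d, silence = %d)\n",
              x$n_videos, x$n_sounds, x$n_repeats, x$blank_video, x$silence))
  cat(sprintf("  trial %.1f s + ITI %.1f s; first onset %.1f s\n",
              x$trial_duration, x$inter_trial_interval, x$trials$onset[1]))
  cat(sprintf("  spontaneous epoch: %.1f-%.1f s\n",
              x$spontaneous_epoch[1], x$spontaneous_epoch[2]))
  invisible(x)
}

#' End time of a schedule
#'
#' The end of the last scheduled event (the spontaneous epoch), i.e. the
#' minimum session duration that covers the schedule.
#' @param schedule a [generate_schedule()] object.
#' @return time in seconds.
#' @export
schedule_end <- function(schedule) schedule$spontaneous_epoch[2]
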
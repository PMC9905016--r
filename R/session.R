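#' Generate a complete synthetic recording session
#'
#' Simulates the four tables a real session provides — spikes, facial
#' motion-energy PCs, eye/pupil signals and trial events — from a stimulus
#' schedule and a [make_ground_truth()] parameter draw, with full knowledge of
#' the generative state so that downstream analyses can be validated by
#' parameter recovery.
#'
#' The generative chain is: a latent state `s(t)` per generative component is
#' the sum of the active sound's kernel on every trial (with per-trial gain
#' jitter) plus slow spontaneous fluctuations; motion PCs are noisy linear
#' readouts of `s(t)`; each neuron's firing rate is
#' `baseline + loadings %*% s(t - lead_time) + visual_code(active video)`,
#' rectified at zero, and spikes are drawn from an inhomogeneous Poisson
#' process. Pupil area couples weakly to the first latent; blinks are rare
#' brief dropouts of the eye signals.
#'
#' @param schedule a [generate_schedule()] object.
#' @param truth a [make_ground_truth()] object.
#' @param duration session length in seconds; defaults to the end of the
#'   schedule's spontaneous epoch plus one second.
#' @param camera_rate face-camera frame rate, Hz (40 in the cortical
#'   recordings emulated here, 60 in others).
#' @param eye_rate eye-camera frame rate, Hz.
#' @param rate_dt time step (s) on which firing rates are evaluated and
#'   Poisson counts drawn.
#' @param seed integer seed; generation is bit-reproducible given the seed
#'   and leaves the caller's RNG state untouched.
#' @return An object of class `synthetic_session`: list with `spikes`
#'   (data.frame `neuron_id`, `spike_time`, sorted), `motion` (list `times`,
#'   `pcs` matrix frames x PCs, `rate`), `eye` (data.frame `time`,
#'   `pupil_area`, `pupil_x`, `pupil_y`, `blink`), `schedule`, `truth`,
#'   `latent` (the noiseless generative state, for oracles) and `duration`.
#' @export
generate_session <- function(schedule, truth, duration = NULL,
                             camera_rate = 40, eye_rate = 100,
                             rate_dt = 0.015, seed = NULL) {
  stopifnot(inherits(schedule, "stim_schedule"), inherits(truth, "ground_truth"))
  if (truth$n_sounds != schedule$n_sounds || truth$n_videos != schedule$n_videos)
    stop_arg("schedule and truth disagree on design counts")
  if (truth$lead_time > schedule$trial_duration)
    stop_arg("lead_time exceeds trial_duration")
  if (is.null(duration)) duration <- schedule_end(schedule) + 1
  need <- max(schedule$trials$onset) + schedule$trial_duration
  if (duration < need || duration < schedule_end(schedule))
    stop_arg("duration does not cover the schedule and spontaneous epoch")

  with_seed(seed, {
    dt <- 0.005
    tt <- seq(0, duration, by = dt)
    n <- length(tt)
    rank <- truth$sound_rank

    # slow spontaneous fluctuations, ~2 Hz low-pass
    s <- smooth_gaussian(matrix(stats::rnorm(n * rank), n, rank), 0.08 / dt)
    s <- sweep(s, 2, apply(s, 2, stats::sd), "/") * truth$spont_sd

    # sparse brief spontaneous movement bursts (whisk-like events)
    br <- if (is.null(truth$spont_burst_rate)) 0 else truth$spont_burst_rate
    n_b <- stats::rpois(1, br * duration)
    if (n_b > 0) {
      b_on <- stats::runif(n_b, 0, duration - 0.5)
      b_th <- stats::runif(n_b, 0.02, 0.06)
      b_amp <- stats::rexp(n_b, 1 / (1.2 * truth$spont_sd))
      b_cmp <- sample.int(rank, n_b, replace = TRUE)
      for (b in seq_len(n_b)) {
        i0 <- floor(b_on[b] / dt) + 1L
        idx <- i0:min(i0 + round(6 * b_th[b] / dt), n)
        u <- (tt[idx] - b_on[b]) / b_th[b]
        s[idx, b_cmp[b]] <- s[idx, b_cmp[b]] + b_amp[b] * u * exp(1 - u)
      }
    }

    # add the sound kernels trial by trial, with per-trial gain jitter
    kdt <- attr(truth$sound_kernels, "dt")
    kt_fine <- seq(0, (dim(truth$sound_kernels)[1] - 1) * kdt, by = dt)
    kern_fine <- lapply(seq_len(truth$n_sounds), function(a) {
      vapply(seq_len(rank), function(j) {
        stats::approx(seq(0, by = kdt, length.out = dim(truth$sound_kernels)[1]),
                      truth$sound_kernels[, a, j], xout = kt_fine, rule = 2)$y
      }, numeric(length(kt_fine)))
    })
    nk <- length(kt_fine)
    tr <- schedule$trials
    gains <- matrix(pmax(0, 1 + stats::rnorm(nrow(tr) * rank, 0, truth$trial_gain_sd)),
                    nrow(tr), rank)
    for (i in seq_len(nrow(tr))) {
      a <- tr$sound_id[i]
      if (a == schedule$silence) next
      i0 <- round(tr$onset[i] / dt) + 1L
      idx <- i0:min(i0 + nk - 1L, n)
      s[idx, ] <- s[idx, ] + kern_fine[[a]][seq_along(idx), , drop = FALSE] *
        rep(gains[i, ], each = length(idx))
    }

    # ---- motion PCs at camera rate ----
    ft <- seq(0, duration, by = 1 / camera_rate)
    s_f <- interp_columns(tt, s, ft)
    motion <- s_f %*% t(truth$motion_loadings) +
      matrix(stats::rnorm(length(ft) * truth$n_motion_pcs, 0, truth$motion_noise_sd),
             length(ft), truth$n_motion_pcs)

    # ---- eye table at eye_rate ----
    et <- seq(0, duration, by = 1 / eye_rate)
    ne <- length(et)
    slow <- function(sdv) {
      x <- smooth_gaussian(matrix(stats::rnorm(ne), ne, 1), 0.3 * eye_rate)
      as.numeric(x) / stats::sd(x) * sdv
    }
    s_e <- interp_columns(tt, s[, 1, drop = FALSE], et)
    area <- 100 + slow(3) + truth$eye_area_gain * as.numeric(s_e)
    ex <- slow(0.5)
    ey <- slow(0.5)
    blink <- integer(ne)
    n_blinks <- stats::rpois(1, truth$blink_rate * duration)
    if (n_blinks > 0) {
      b_on <- stats::runif(n_blinks, 0, duration - 0.3)
      b_dur <- stats::runif(n_blinks, 0.1, 0.3)
      for (b in seq_len(n_blinks)) {
        sel <- et >= b_on[b] & et <= b_on[b] + b_dur[b]
        blink[sel] <- 1L
        area[sel] <- 0
        ex[sel] <- 0
        ey[sel] <- 0
      }
    }
    eye <- data.frame(time = et, pupil_area = area, pupil_x = ex, pupil_y = ey,
                      blink = blink)

    # ---- firing rates and Poisson spikes ----
    rt <- seq(0, duration - rate_dt, by = rate_dt) + rate_dt / 2
    s_shift <- interp_columns(tt, s, rt - truth$lead_time)
    rates <- matrix(rep(truth$baseline_rates, each = length(rt)),
                    length(rt), truth$n_neurons)
    rates <- rates + s_shift %*% t(truth$neural_loadings)
    code <- truth$visual_code
    cdt <- attr(code, "dt")
    nb_code <- dim(code)[1]
    for (i in seq_len(nrow(tr))) {
      v <- tr$video_id[i]
      if (v == schedule$blank_video) next
      i0 <- max(1L, ceiling(tr$onset[i] / rate_dt + 0.5))
      i1 <- min(length(rt),
                floor((tr$onset[i] + schedule$trial_duration) / rate_dt + 0.5))
      if (i1 < i0) next
      rows <- i0:i1
      pos <- (rt[rows] - tr$onset[i]) / cdt
      i0 <- pmin(floor(pos) + 1L, nb_code - 1L)
      fr <- pos - (i0 - 1L)
      cv <- code[, v, , drop = TRUE]
      rates[rows, ] <- rates[rows, ] + cv[i0, , drop = FALSE] * (1 - fr) +
        cv[i0 + 1L, , drop = FALSE] * fr
    }
    rates[rates < 0] <- 0
    counts <- stats::rpois(length(rates), rates * rate_dt)
    nz <- which(counts > 0L)
    reps <- counts[nz]
    bin_idx <- ((nz - 1L) %% length(rt)) + 1L
    cell_idx <- ((nz - 1L) %/% length(rt)) + 1L
    st <- rep(rt[bin_idx] - rate_dt / 2, reps) +
      stats::runif(sum(reps)) * rate_dt
    sc <- rep(cell_idx, reps)
    o <- order(sc, st)
    spikes <- data.frame(neuron_id = sc[o], spike_time = st[o])

    structure(list(
      spikes = spikes,
      motion = list(times = ft, pcs = motion, rate = camera_rate),
      eye = eye,
      schedule = schedule,
      truth = truth,
      latent = list(times = tt, values = s),
      duration = duration,
      seed = seed
    ), class = "synthetic_session")
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat("Synthetic session:", x$duration, "s,",
      x$truth$n_neurons, "neurons,", nrow(x$spikes), "spikes\n")
  cat(sprintf("  %d trials; motion: %d PCs @ %g Hz; eye @ %g Hz\n",
              nrow(x$schedule$trials), ncol(x$motion$pcs), x$motion$rate,
              1 / diff(x$eye$time[1:2])))
  print(x$schedule)
  invisible(x)
}

#' Write / read a synthetic session as CSV tables
#'
#' `write_session()` writes four plain-text tables (`spikes.csv`,
#' `motion.csv`, `eye.csv`, `events.csv`) plus a `meta.yaml` with the design
#' counts and timing parameters; `read_session()` reads them back. Ground
#' truth is not serialized (it lives in the R object).
#'
#' @param session a `synthetic_session`.
#' @param dir directory to write into (created if missing).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a list with `spikes`, `motion`, `eye`, `schedule`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  mo <- data.frame(time = session$motion$times, session$motion$pcs)
  names(mo) <- c("time", paste0("pc", seq_len(ncol(session$motion$pcs))))
  utils::write.csv(mo, file.path(dir, "motion.csv"), row.names = FALSE)
  utils::write.csv(session$eye, file.path(dir, "eye.csv"), row.names = FALSE)
  utils::write.csv(session$schedule$trials, file.path(dir, "events.csv"),
                   row.names = FALSE)
  sch <- session$schedule
  meta <- list(n_videos = sch$n_videos, n_sounds = sch$n_sounds,
               n_repeats = sch$n_repeats, trial_duration = sch$trial_duration,
               inter_trial_interval = sch$inter_trial_interval,
               spontaneous_epoch = as.numeric(sch$spontaneous_epoch),
               camera_rate = session$motion$rate,
               duration = session$duration)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  trials <- utils::read.csv(file.path(dir, "events.csv"))
  sched <- structure(list(
    trials = trials,
    n_videos = meta$n_videos, n_sounds = meta$n_sounds,
    n_repeats = meta$n_repeats,
    trial_duration = meta$trial_duration,
    inter_trial_interval = meta$inter_trial_interval,
    spontaneous_epoch = unlist(meta$spontaneous_epoch),
    blank_video = meta$n_videos, silence = meta$n_sounds,
    seed = NULL
  ), class = "stim_schedule")
  mo <- utils::read.csv(file.path(dir, "motion.csv"))
  list(
    spikes = utils::read.csv(file.path(dir, "spikes.csv")),
    motion = list(times = mo$time,
                  pcs = as.matrix(mo[, -1, drop = FALSE]),
                  rate = meta$camera_rate),
    eye = utils::read.csv(file.path(dir, "eye.csv")),
    schedule = sched,
    duration = meta$duration
  )
}
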
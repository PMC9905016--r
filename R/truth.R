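#' Ground-truth parameters for a synthetic session
#'
#' Draws the latent structure that a synthetic session is generated from and
#' that downstream analyses are expected to recover. The generative model is:
#' each sound owns `sound_rank` latent time courses (sums of 2-4 gamma-shaped
#' bumps within ~1 s of onset; silence has none); the latents drive the facial
#' motion-energy PCs through `motion_loadings` and, `lead_time` seconds later,
#' the neurons through `neural_loadings`. Videos drive neurons through
#' high-rank smooth per-(video, neuron) time courses (`visual_code`), scaled
#' so that video-related variance dominates sound-related variance, as in
#' cortical recordings. Spiking is inhomogeneous Poisson around gamma-drawn
#' baseline rates.
#'
#' @param n_neurons number of simulated neurons.
#' @param n_motion_pcs number of facial motion-energy principal components.
#' @param n_sounds,n_videos design counts; the last sound is silence and the
#'   last video is the blank screen (both carry no evoked signal).
#' @param sound_rank generative rank of the sound-evoked latent across
#'   neurons (1 = one shared time course per sound up to gain).
#' @param kernel_amp overall amplitude of the sound kernels (latent units).
#' @param lead_time seconds by which the behavioral latent precedes its
#'   neural consequence (movement leads the neurons).
#' @param baseline_rate_mean,baseline_rate_shape gamma parameters of the
#'   per-neuron baseline firing rates (spikes/s).
#' @param neural_gain_mean,neural_gain_sd normal parameters of the per-neuron
#'   loadings on each latent (spikes/s per latent unit); the positive mean
#'   emulates the predominantly excitatory population weights seen in vivo.
#' @param visual_amp amplitude (spikes/s, SD) of the per-video neural time
#'   courses.
#' @param spont_sd SD of the slow spontaneous latent fluctuations (latent
#'   units), low-pass filtered at roughly 2 Hz.
#' @param spont_burst_rate rate (Hz) of brief spontaneous movement bursts
#'   (sharp gamma-shaped events, ~50-150 ms wide) superimposed on the slow
#'   fluctuations; these emulate spontaneous whisk/twitch events and give
#'   the spontaneous behavior the fast temporal structure that makes
#'   movement-to-neural lags identifiable at the camera frame rate.
#' @param motion_noise_sd SD of the white noise added to each motion PC.
#' @param trial_gain_sd SD of the per-trial multiplicative gain jitter on the
#'   sound-evoked latent (trial-to-trial behavioral variability).
#' @param eye_area_gain coupling of pupil area to the first latent.
#' @param blink_rate rate of blink events (Hz); blinks are 100-300 ms
#'   dropouts of the eye signals.
#' @param pixel_mask_dim dimensions (rows, cols) of the per-motion-PC
#'   abstract spatial weight images, used by [pixel_weight_map()].
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return An object of class `ground_truth` (a list of the drawn parameters;
#'   `sound_kernels` is an array time x sound x component sampled at
#'   `attr(,"dt")` seconds).
#' @export
make_ground_truth <- function(n_neurons = 80, n_motion_pcs = 128,
                              n_sounds = 12, n_videos = 12,
                              sound_rank = 1, kernel_amp = 4,
                              lead_time = 0.030,
                              baseline_rate_mean = 20, baseline_rate_shape = 8,
                              neural_gain_mean = 1.0, neural_gain_sd = 0.6,
                              visual_amp = 5,
                              spont_sd = 1.0, spont_burst_rate = 0.4,
                              motion_noise_sd = 0.5,
                              trial_gain_sd = 0.3,
                              eye_area_gain = 0.5, blink_rate = 0.1,
                              pixel_mask_dim = c(16, 16),
                              seed = NULL) {
  if (n_neurons < 1 || n_motion_pcs < 1 || sound_rank < 1)
    stop_arg("counts must be >= 1")
  with_seed(seed, {
    dt <- 0.01
    kt <- seq(0, 1.2, by = dt)
    kernels <- array(0, dim = c(length(kt), n_sounds, sound_rank))
    for (a in seq_len(n_sounds - 1)) {      # last sound is silence: kernel 0
      for (j in seq_len(sound_rank)) {
        nb <- sample(2:4, 1)
        k <- numeric(length(kt))
        for (b in seq_len(nb)) {
          onset <- stats::runif(1, 0.02, 0.7)
          theta <- stats::runif(1, 0.04, 0.15)
          amp <- stats::runif(1, 0.4, 1.3) * kernel_amp
          u <- (kt - onset) / theta
          k <- k + ifelse(u > 0, amp * u * exp(1 - u), 0)
        }
        kernels[, a, j] <- k
      }
    }
    attr(kernels, "dt") <- dt

    # per-neuron loadings on each latent: positive mean per component, and
    # for multi-component truths near-orthogonal directions of comparable
    # size, so the generative rank is expressed cleanly across the population
    w <- matrix(stats::rnorm(n_neurons * sound_rank,
                             mean = neural_gain_mean, sd = neural_gain_sd),
                n_neurons, sound_rank)
    if (sound_rank > 1) {
      for (j in 2:sound_rank) {
        wj <- stats::rnorm(n_neurons, 0, 1)
        prev <- w[, seq_len(j - 1), drop = FALSE]
        wj <- wj - prev %*% solve(crossprod(prev), crossprod(prev, wj))
        if (mean(wj) < 0) wj <- -wj
        w[, j] <- wj / sqrt(sum(wj^2)) * sqrt(sum(w[, 1]^2))
      }
    }

    # motion-PC loadings: PC1 carries the latents strongly and positively,
    # higher PCs load with decaying random weights
    ml <- matrix(stats::rnorm(n_motion_pcs * sound_rank), n_motion_pcs, sound_rank)
    decay <- 1.5 / (seq_len(n_motion_pcs) + 1)
    ml <- ml * decay
    ml[1, ] <- 0.25
    ml[1, 1] <- 1.2
    if (sound_rank > 1) {
      # let each extra latent dominate one distinct early PC so the motion
      # code spans the full generative rank
      for (j in 2:min(sound_rank, n_motion_pcs)) ml[j, j] <- 1.0
    }

    baseline <- stats::rgamma(n_neurons, shape = baseline_rate_shape,
                              rate = baseline_rate_shape / baseline_rate_mean)

    # per-(video, neuron) response time courses: smooth shared temporal
    # bases mixed with power-law channel weights, so the population video
    # code is high-dimensional with a realistic decaying eigenspectrum and
    # a dominant first component; the blank video evokes nothing
    dt_code <- 0.02
    nb_code <- length(seq(0, 4, by = dt_code))
    vis <- array(0, dim = c(nb_code, n_videos, n_neurons))
    vis_scale <- visual_amp * stats::rgamma(n_neurons, 4, 4)
    K <- min(n_neurons, 40L)
    for (v in seq_len(n_videos - 1)) {
      U <- smooth_gaussian(matrix(stats::rnorm(nb_code * K), nb_code, K),
                           0.1 / dt_code)
      U <- sweep(U, 2, apply(U, 2, stats::sd), "/")
      Bw <- matrix(stats::rnorm(K * n_neurons), K, n_neurons) *
        seq_len(K)^(-0.6)
      Bw[1, ] <- stats::rnorm(n_neurons, mean = 2, sd = 0.7)
      cv <- U %*% Bw
      sdv <- apply(cv, 2, stats::sd)
      sdv[sdv == 0] <- 1
      vis[, v, ] <- sweep(sweep(cv, 2, sdv, "/"), 2, vis_scale, "*")
    }
    attr(vis, "dt") <- dt_code

    masks <- matrix(stats::rnorm(n_motion_pcs * prod(pixel_mask_dim)),
                    n_motion_pcs, prod(pixel_mask_dim))

    structure(list(
      n_neurons = n_neurons, n_motion_pcs = n_motion_pcs,
      n_sounds = n_sounds, n_videos = n_videos,
      sound_rank = sound_rank,
      sound_kernels = kernels,
      neural_loadings = w,
      motion_loadings = ml,
      lead_time = lead_time,
      baseline_rates = baseline,
      visual_code = vis,
      spont_sd = spont_sd, spont_burst_rate = spont_burst_rate,
      motion_noise_sd = motion_noise_sd,
      trial_gain_sd = trial_gain_sd,
      eye_area_gain = eye_area_gain, blink_rate = blink_rate,
      pixel_masks = masks, pixel_mask_dim = pixel_mask_dim,
      seed = seed
    ), class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", x$n_neurons, "neurons,", x$n_motion_pcs, "motion PCs\n")
  cat(sprintf("  sound rank %d, lead time %.0f ms, mean neural loading %.2f\n",
              x$sound_rank, 1000 * x$lead_time, mean(x$neural_loadings)))
  invisible(x)
}
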
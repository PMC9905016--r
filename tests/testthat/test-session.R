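test_that("session generation is bit-reproducible given a seed", {
  sched <- generate_schedule(2, 2, 2, spontaneous_duration = 20, seed = 1)
  truth <- make_ground_truth(n_neurons = 4, n_motion_pcs = 3, n_videos = 2,
                             n_sounds = 2, seed = 2)
  s1 <- generate_session(sched, truth, seed = 3)
  s2 <- generate_session(sched, truth, seed = 3)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$motion$pcs, s2$motion$pcs)
  expect_identical(s1$eye, s2$eye)
  s3 <- generate_session(sched, truth, seed = 4)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("spike and sample tables satisfy their ordering invariants", {
  sched <- generate_schedule(2, 2, 2, spontaneous_duration = 20, seed = 1)
  truth <- make_ground_truth(n_neurons = 4, n_motion_pcs = 3, n_videos = 2,
                             n_sounds = 2, seed = 2)
  ses <- generate_session(sched, truth, seed = 3)
  sp <- ses$spikes
  expect_true(all(sp$spike_time >= 0))
  expect_true(all(diff(sp$neuron_id) >= 0))
  for (id in unique(sp$neuron_id))
    expect_true(!is.unsorted(sp$spike_time[sp$neuron_id == id]))
  expect_true(all(diff(ses$motion$times) > 0))
  expect_true(all(diff(ses$eye$time) > 0))
  # spontaneous epoch has no onsets but carries latent fluctuations
  ep <- sched$spontaneous_epoch
  expect_false(any(sched$trials$onset >= ep[1] & sched$trials$onset <= ep[2]))
  lat <- ses$latent$values[ses$latent$times >= ep[1] &
                             ses$latent$times <= ep[2], 1]
  expect_gt(sd(lat), 0)
})

test_that("a drive-free truth yields statistically flat Poisson rates", {
  sched <- generate_schedule(2, 2, 2, spontaneous_duration = 20, seed = 1)
  truth <- make_ground_truth(n_neurons = 5, n_motion_pcs = 2, n_videos = 2,
                             n_sounds = 2, kernel_amp = 0, visual_amp = 0,
                             spont_sd = 0, spont_burst_rate = 0, seed = 6)
  ses <- generate_session(sched, truth, seed = 7)
  for (c in 1:5) {
    n_sp <- sum(ses$spikes$neuron_id == c)
    expected <- truth$baseline_rates[c] * ses$duration
    expect_lt(abs(n_sp - expected), 3.5 * sqrt(expected))
  }
})

test_that("a single planted kernel raises rates by w_c * k within Poisson error", {
  # sound 1 carries one kernel; sound 2 is silence; video 1 is blank;
  # no trial jitter, no spontaneous drive: closed-form Poisson expectation
  sched <- generate_schedule(1, 2, 20, spontaneous_duration = 10,
                             first_onset = 2, seed = 11)
  truth <- make_ground_truth(n_neurons = 6, n_motion_pcs = 2, n_videos = 1,
                             n_sounds = 2, visual_amp = 0, spont_sd = 0,
                             spont_burst_rate = 0, trial_gain_sd = 0,
                             seed = 12)
  ses <- generate_session(sched, truth, seed = 13)
  kdt <- attr(truth$sound_kernels, "dt")
  k_area <- sum(truth$sound_kernels[, 1, 1]) * kdt   # integral of the kernel
  tr <- ses$schedule$trials
  count_in <- function(onsets, c) {
    s <- ses$spikes[ses$spikes$neuron_id == c, "spike_time"]
    sum(vapply(onsets, function(o) sum(s >= o & s < o + 1.5), 0))
  }
  on1 <- tr$onset[tr$sound_id == 1]
  on2 <- tr$onset[tr$sound_id == 2]
  for (c in 1:6) {
    extra <- count_in(on1, c) - count_in(on2, c)
    expected <- truth$neural_loadings[c, 1] * k_area * length(on1)
    se <- sqrt(2 * truth$baseline_rates[c] * 1.5 * length(on1) +
                 abs(expected))
    expect_lt(abs(extra - expected), 4 * se)
  }
})

test_that("motion leads the neural drive by the configured lead time", {
  sched <- generate_schedule(3, 3, 2, spontaneous_duration = 120, seed = 21)
  truth <- make_ground_truth(n_neurons = 4, n_motion_pcs = 3, n_videos = 3,
                             n_sounds = 3, lead_time = 0.030, seed = 22)
  ses <- generate_session(sched, truth, seed = 23)
  # oracle: cross-correlate the noiseless latent against its own delayed
  # copy on the camera frame grid; the peak must sit at the frame nearest
  # the 30 ms lead (one 25 ms frame)
  ft <- ses$motion$times
  x <- approx(ses$latent$times, ses$latent$values[, 1], xout = ft, rule = 2)$y
  y <- approx(ses$latent$times, ses$latent$values[, 1],
              xout = ft - truth$lead_time, rule = 2)$y
  xc <- xcorr_lag(x, y, rate = ses$motion$rate, max_lag = 0.5)
  expect_equal(xc$lag, 0.025, tolerance = 1e-9)
  # and the generated (noisy) motion PC1 against the same delayed latent
  xc2 <- xcorr_lag(ses$motion$pcs[, 1], y, rate = ses$motion$rate,
                   max_lag = 0.5)
  expect_true(xc2$lag >= 0.025 - 1e-9 && xc2$lag <= 0.050 + 1e-9)
})

test_that("sessions survive a CSV round trip", {
  sched <- generate_schedule(2, 2, 2, spontaneous_duration = 15, seed = 31)
  truth <- make_ground_truth(n_neurons = 3, n_motion_pcs = 2, n_videos = 2,
                             n_sounds = 2, seed = 32)
  ses <- generate_session(sched, truth, seed = 33)
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  expect_setequal(list.files(dir), c("spikes.csv", "motion.csv", "eye.csv",
                                     "events.csv", "meta.yaml"))
  back <- read_session(dir)
  expect_equal(back$spikes$spike_time, ses$spikes$spike_time)
  expect_equal(back$motion$pcs, ses$motion$pcs, ignore_attr = TRUE)
  expect_equal(back$schedule$trials$onset, ses$schedule$trials$onset)
  expect_equal(back$schedule$n_sounds, 2)
})

test_that("inconsistent arguments are rejected", {
  sched <- generate_schedule(2, 2, 2, spontaneous_duration = 15, seed = 41)
  truth <- make_ground_truth(n_neurons = 3, n_motion_pcs = 2, n_videos = 2,
                             n_sounds = 2, seed = 42)
  expect_error(generate_session(sched, truth, duration = 10), "duration")
  truth_bad <- make_ground_truth(n_neurons = 3, n_motion_pcs = 2, n_videos = 2,
                                 n_sounds = 2, lead_time = 10, seed = 43)
  expect_error(generate_session(sched, truth_bad, seed = 44), "lead_time")
  truth_mism <- make_ground_truth(n_neurons = 3, n_motion_pcs = 2,
                                  n_sounds = 5, seed = 45)
  expect_error(generate_session(sched, truth_mism, seed = 46), "disagree")
})
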
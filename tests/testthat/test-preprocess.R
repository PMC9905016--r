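test_that("causal half-Gaussian smoothing has unit DC gain and is causal", {
  # constant input -> constant output
  y <- smooth_causal_half_gaussian(rep(3.7, 50), sigma = 0.043, dt = 0.03)
  expect_equal(y, rep(3.7, 50), tolerance = 1e-12)
  # unit impulse far from the edge -> the normalized truncated kernel
  x <- numeric(60); x[30] <- 1
  y <- smooth_causal_half_gaussian(x, sigma = 0.043, dt = 0.03)
  L <- ceiling(4 * 0.043 / 0.03)
  g <- exp(-((0:L) * 0.03)^2 / (2 * 0.043^2)); g <- g / sum(g)
  expect_equal(y[30:(30 + L)], g, tolerance = 1e-12)
  expect_true(all(y[1:29] == 0))
})

test_that("smoothing equals the brute-force truncated convolution", {
  set.seed(101)
  x <- rnorm(80)
  y <- smooth_causal_half_gaussian(x, sigma = 0.043, dt = 0.03)
  # oracle: direct double loop over the documented formula
  L <- ceiling(4 * 0.043 / 0.03)
  g <- exp(-((0:L) * 0.03)^2 / (2 * 0.043^2)); g <- g / sum(g)
  oracle <- numeric(80)
  for (t in 1:80) {
    jmax <- min(L, t - 1)
    num <- 0
    for (j in 0:jmax) num <- num + g[j + 1] * x[t - j]
    oracle[t] <- num / sum(g[1:(jmax + 1)])
  }
  expect_equal(y, oracle, tolerance = 1e-12)
})

test_that("perturbing one sample only changes the smoothed output at later bins", {
  set.seed(102)
  x <- rnorm(60)
  x2 <- x; x2[25] <- x2[25] + 1
  y1 <- smooth_causal_half_gaussian(x, 0.043, 0.03)
  y2 <- smooth_causal_half_gaussian(x2, 0.043, 0.03)
  expect_equal(y1[1:24], y2[1:24])
  expect_false(isTRUE(all.equal(y1[25:60], y2[25:60])))
})

test_that("smoothing rejects bad sampling arguments", {
  expect_error(smooth_causal_half_gaussian(1:10, sigma = 0, dt = 0.03), "sigma")
  expect_error(smooth_causal_half_gaussian(1:10, sigma = 0.04, dt = 0.03,
                                           times = c(0, 1, 3)), "non-uniform")
})

test_that("binned counts match their construction and z-scores are standard", {
  # spikes exactly every 30 ms -> one count per bin before standardization
  sp <- data.frame(neuron_id = 1L, spike_time = seq(0.015, 2.985, by = 0.03))
  b <- bin_and_zscore(sp, 1, bin_size = 0.03, sigma = NULL, t_end = 3,
                      zscore = FALSE)
  expect_true(all(b$traces == 1))
  # empty table: zeros and a warning
  expect_warning(
    b0 <- bin_and_zscore(data.frame(neuron_id = integer(0),
                                    spike_time = numeric(0)),
                         2, t_end = 3),
    "zero variance")
  expect_true(all(b0$traces == 0))
  # Poisson neuron at 10 spikes/s: mean raw count/bin near 0.3
  set.seed(103)
  n_sp <- rpois(1, 10 * 200)
  sp <- data.frame(neuron_id = 1L, spike_time = sort(runif(n_sp, 0, 200)))
  b <- bin_and_zscore(sp, 1, bin_size = 0.03, sigma = NULL, t_end = 200,
                      zscore = FALSE)
  se <- sqrt(0.3 / nrow(b$traces))
  expect_lt(abs(mean(b$traces) - 0.3), 3 * se)
  # z-scored traces have mean 0 and sd 1 over the session; re-standardizing
  # is the identity
  bz <- bin_and_zscore(sp, 1, bin_size = 0.03, t_end = 200)
  expect_lt(abs(mean(bz$traces)), 1e-6)
  expect_lt(abs(sd(bz$traces) - 1), 1e-6)
})

test_that("eye channels follow their closed-form constructions", {
  sched <- generate_schedule(2, 2, 2, first_onset = 3,
                             spontaneous_duration = 5, seed = 111)
  t_end <- schedule_end(sched) + 1
  tt <- seq(0, t_end, by = 0.01)
  # constant position: motion channels identically zero, baseline-corrected
  # positions identically zero
  eye <- data.frame(time = tt, pupil_area = 50, pupil_x = 2, pupil_y = -1,
                    blink = 0L)
  E <- derive_eye_channels(eye, sched, t_end = t_end)
  expect_equal(dim(E)[5], 9)
  expect_true(all(abs(E[, , , , 2:8]) < 1e-12))
  # ramp: slope m per bin -> signed motion m, unsigned |m|, global m*sqrt(2)
  m <- 0.06  # per 30 ms bin (ramp slope 2 units/s)
  eye <- data.frame(time = tt, pupil_area = 50, pupil_x = 2 * tt,
                    pupil_y = 2 * tt, blink = 0L)
  E <- derive_eye_channels(eye, sched, t_end = t_end)
  expect_equal(max(abs(E[, , , , 4] - m)), 0, tolerance = 1e-9)
  expect_equal(max(abs(E[, , , , 6] - m)), 0, tolerance = 1e-9)
  expect_equal(max(abs(E[, , , , 8] - m * sqrt(2))), 0, tolerance = 1e-9)
  # unsigned channels are non-negative by construction
  expect_true(all(E[, , , , 6:8] >= 0))
  # baseline correction: pre-onset mean of corrected channels is zero
  pre <- attr(E, "rel_times") < 0
  expect_lt(max(abs(apply(E[pre, , , , 2:3, drop = FALSE],
                          c(2, 3, 4, 5), mean))), 1e-9)
})

test_that("blink samples are interpolated on the line between valid samples", {
  tt <- seq(0, 1, by = 0.01)
  v <- sin(tt * 5)
  blink <- integer(length(tt)); blink[11:14] <- 1L
  out <- soundmotion:::interpolate_blinks(tt, v, blink)
  slope <- (v[15] - v[10]) / (tt[15] - tt[10])
  expect_equal(out[11:14], v[10] + slope * (tt[11:14] - tt[10]),
               tolerance = 1e-12)
  expect_equal(out[-(11:14)], v[-(11:14)])
})

test_that("tensor assembly is a pure re-indexing of the traces", {
  sched <- generate_schedule(2, 3, 2, first_onset = 3,
                             spontaneous_duration = 5, seed = 121)
  t_end <- schedule_end(sched) + 1
  n_bins <- floor(t_end / 0.03)
  times <- (seq_len(n_bins) - 1) * 0.03
  set.seed(122)
  traces <- matrix(rnorm(n_bins * 4), n_bins, 4)
  D <- assemble_trial_tensor(traces, times, sched)
  expect_equal(dim(D), c(160, 2, 3, 2, 4))
  # sum over the tensor equals the sum over the corresponding segments
  total <- 0
  for (i in seq_len(nrow(sched$trials))) {
    ob <- floor(sched$trials$onset[i] / 0.03) + 1
    total <- total + sum(traces[(ob - 33):(ob + 126), ])
  }
  expect_equal(sum(D), total, tolerance = 1e-9)
  # invariance to the ordering of the input trial table
  sched2 <- sched
  set.seed(123)
  sched2$trials <- sched2$trials[sample(nrow(sched2$trials)), ]
  D2 <- assemble_trial_tensor(traces, times, sched2)
  expect_equal(unclass(D), unclass(D2))
  # a one-trial schedule is direct slicing
  sched1 <- generate_schedule(1, 1, 1, first_onset = 3,
                              spontaneous_duration = 2, seed = 124)
  D1 <- assemble_trial_tensor(traces, times, sched1)
  ob <- floor(3 / 0.03) + 1
  expect_equal(dim(D1), c(160, 1, 1, 1, 4))
  expect_equal(D1[, 1, 1, 1, ], traces[(ob - 33):(ob + 126), ])
})

test_that("an incomplete design is rejected with the missing pairs named", {
  sched <- generate_schedule(2, 2, 2, first_onset = 3,
                             spontaneous_duration = 5, seed = 131)
  sched$trials <- sched$trials[-1, ]
  n_bins <- floor(schedule_end(sched) / 0.03)
  traces <- matrix(0, n_bins, 2)
  times <- (seq_len(n_bins) - 1) * 0.03
  expect_error(assemble_trial_tensor(traces, times, sched), "incomplete design")
  # and a window reaching before the recording start
  sched0 <- generate_schedule(1, 1, 1, first_onset = 0.2,
                              spontaneous_duration = 2, seed = 132)
  expect_error(assemble_trial_tensor(traces, times, sched0), "outside")
})
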
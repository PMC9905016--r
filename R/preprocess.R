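#' Causal half-Gaussian smoothing
#'
#' Smooths a uniformly sampled trace (or each column of a matrix) with a
#' Gaussian kernel truncated to non-negative lags, so the output at time `t`
#' depends only on samples at or before `t`. The kernel is normalized to unit
#' sum (DC gain 1); at the first few samples the truncated kernel is
#' renormalized over the available history so a constant input stays constant.
#'
#' @param x numeric vector or matrix (time in rows).
#' @param sigma kernel standard deviation, seconds.
#' @param dt sampling interval, seconds. If `times` is supplied it is checked
#'   for uniformity instead.
#' @param times optional sample times; non-uniform spacing is an error.
#' @return smoothed vector/matrix, same shape as `x`.
#' @export
smooth_causal_half_gaussian <- function(x, sigma, dt, times = NULL) {
  if (!is.null(times)) {
    d <- diff(times)
    if (max(d) - min(d) > 1e-9 * max(abs(d)))
      stop_arg("non-uniform sampling")
    dt <- d[1]
  }
  if (!is.numeric(sigma) || sigma <= 0) stop_arg("sigma must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop_arg("dt must be > 0")
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  L <- ceiling(4 * sigma / dt)
  g <- exp(-((0:L) * dt)^2 / (2 * sigma^2))
  g <- g / sum(g)
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (j in 0:min(L, n - 1L)) {
    rows <- (j + 1L):n
    out[rows, ] <- out[rows, ] + g[j + 1L] * x[rows - j, , drop = FALSE]
  }
  # renormalize the leading edge where the kernel is cut short
  gc <- cumsum(g)
  edge <- seq_len(min(L, n))
  out[edge, ] <- out[edge, , drop = FALSE] / gc[edge]
  if (vec) as.numeric(out) else out
}

#' Bin spike times, smooth, and z-score per neuron
#'
#' Counts spikes in half-open bins `[t, t + bin_size)` over the whole
#' session, smooths each neuron's count trace with a causal half-Gaussian
#' filter, and z-scores it over the full session. Neurons with no spikes get
#' an all-zero trace and a warning.
#'
#' @param spikes data.frame with columns `neuron_id` (1-based integers) and
#'   `spike_time` (seconds).
#' @param n_neurons number of neurons (ids may be absent from `spikes`).
#' @param bin_size bin width, seconds.
#' @param sigma causal half-Gaussian SD, seconds; `NULL` or 0 skips smoothing.
#' @param t_start,t_end session span covered by the binning, seconds.
#' @param zscore standardize each trace over the full session (default TRUE).
#' @return list with `traces` (bins x neurons), `times` (bin start times),
#'   `bin_size`, and the standardization constants `center`/`scale`.
#' @export
bin_and_zscore <- function(spikes, n_neurons, bin_size = 0.030, sigma = 0.043,
                           t_start = 0, t_end, zscore = TRUE) {
  stopifnot(all(c("neuron_id", "spike_time") %in% names(spikes)))
  if (nrow(spikes) > 0 &&
      (min(spikes$spike_time) < t_start || max(spikes$spike_time) > t_end))
    stop_arg("spike times outside [t_start, t_end]")
  n_bins <- floor((t_end - t_start) / bin_size)
  times <- t_start + (seq_len(n_bins) - 1) * bin_size
  bin_idx <- floor((spikes$spike_time - t_start) / bin_size) + 1L
  keep <- bin_idx >= 1L & bin_idx <= n_bins
  flat <- (as.integer(spikes$neuron_id[keep]) - 1L) * n_bins + bin_idx[keep]
  counts <- matrix(tabulate(flat, nbins = n_bins * n_neurons), n_bins, n_neurons)
  traces <- counts
  if (!is.null(sigma) && sigma > 0)
    traces <- smooth_causal_half_gaussian(traces, sigma, bin_size)
  center <- rep(0, n_neurons)
  scale <- rep(1, n_neurons)
  if (zscore) {
    traces <- zscore_columns(traces, warn_label = "neuron")
    center <- attr(traces, "center")
    scale <- attr(traces, "scale")
    attr(traces, "center") <- NULL
    attr(traces, "scale") <- NULL
  }
  list(traces = traces, times = times, bin_size = bin_size,
       center = center, scale = scale)
}

# Interpolate blink-flagged samples of a vector from the surrounding valid
# samples (linear; constant extrapolation at record edges).
interpolate_blinks <- function(time, value, blink) {
  bad <- blink > 0
  if (!any(bad)) return(value)
  if (all(bad)) stop_arg("all samples are blinks")
  value[bad] <- stats::approx(time[!bad], value[!bad], xout = time[bad],
                              rule = 2)$y
  value
}

# Continuous 9-channel eye matrix on the analysis bin grid:
# pupil_area, pupil_x, pupil_y, signed x/y motion, unsigned x/y motion,
# global (L2) motion, blink flag. Motion is the between-bin difference of the
# blink-interpolated positions.
bin_eye_channels <- function(eye, bin_size, t_end) {
  area <- interpolate_blinks(eye$time, eye$pupil_area, eye$blink)
  px <- interpolate_blinks(eye$time, eye$pupil_x, eye$blink)
  py <- interpolate_blinks(eye$time, eye$pupil_y, eye$blink)
  n_bins <- floor(t_end / bin_size)
  bt <- (seq_len(n_bins) - 1) * bin_size + bin_size / 2
  b <- interp_columns(eye$time, cbind(area, px, py), bt)
  mx <- c(0, diff(b[, 2]))
  my <- c(0, diff(b[, 3]))
  blink_b <- as.numeric(interp_columns(eye$time, cbind(as.numeric(eye$blink)), bt) > 0.5)
  out <- cbind(b[, 1], b[, 2], b[, 3], mx, my, abs(mx), abs(my),
               sqrt(mx^2 + my^2), blink_b)
  colnames(out) <- c("pupil_area", "pupil_x", "pupil_y",
                     "eye_motion_x", "eye_motion_y",
                     "eye_motion_x_abs", "eye_motion_y_abs",
                     "eye_motion_global", "blink")
  list(traces = out, times = (seq_len(n_bins) - 1) * bin_size,
       bin_size = bin_size)
}

#' Derive the 9 per-trial eye channels
#'
#' Builds the behavioral trial tensor of eye-derived channels: pupil area and
#' x/y position (baseline-corrected by subtracting each trial's mean over the
#' second preceding onset), signed and unsigned between-bin eye motion,
#' global (L2) motion, and the blink flag. Blink-flagged samples of the raw
#' signals are linearly interpolated from the nearest valid samples before
#' motion is computed.
#'
#' @param eye eye table: data.frame `time`, `pupil_area`, `pupil_x`,
#'   `pupil_y`, `blink`.
#' @param schedule a [generate_schedule()] object covering all trials.
#' @param bin_size,window,t_end trial-tensor conventions (see
#'   [assemble_trial_tensor()]); `t_end` defaults to the last eye sample.
#' @return a `trial_tensor` (time x video x sound x repeat x 9 channels) of
#'   kind `"behavioral"`.
#' @export
derive_eye_channels <- function(eye, schedule, bin_size = 0.030,
                                window = c(-1, 3.8), t_end = max(eye$time)) {
  b <- bin_eye_channels(eye, bin_size, t_end)
  assemble_trial_tensor(b$traces, b$times, schedule, window = window,
                        bin_size = bin_size, channel_kind = "behavioral",
                        channel_ids = colnames(b$traces),
                        baseline_channels = 1:3)
}

#' Assemble a peri-stimulus trial tensor
#'
#' Slices full-session channel traces around each trial onset into the 5-way
#' array `D[t, v, a, r, c]` (time bin x video x sound x repeat x channel)
#' that all downstream stages operate on. The design must be complete: every
#' (video, sound) pair must occur exactly `n_repeats` times. The repeat index
#' preserves presentation order within each pair, and assembly is invariant
#' to the ordering of the input trial table.
#'
#' @param traces bins x channels matrix of full-session traces.
#' @param times bin start times (uniform grid starting at the session start).
#' @param schedule a [generate_schedule()] object.
#' @param window peri-stimulus window (start, end) in seconds relative to
#'   onset; the default (-1, 3.8) with 30 ms bins gives 160 bins.
#' @param bin_size bin width, seconds (must match `times`).
#' @param channel_kind `"neuron"` or `"behavioral"`.
#' @param channel_ids channel labels.
#' @param baseline_channels optional channel indices whose per-trial mean
#'   over the second preceding onset is subtracted (pupil conventions).
#' @return object of class `trial_tensor`: the 5-way array with attributes
#'   `bin_size`, `window`, `rel_times`, `channel_kind`, `channel_ids`.
#' @export
assemble_trial_tensor <- function(traces, times, schedule,
                                  window = c(-1, 3.8), bin_size = 0.030,
                                  channel_kind = c("neuron", "behavioral"),
                                  channel_ids = NULL,
                                  baseline_channels = NULL) {
  channel_kind <- match.arg(channel_kind)
  traces <- as.matrix(traces)
  n_t <- round((window[2] - window[1]) / bin_size)
  off0 <- round(window[1] / bin_size)
  offsets <- off0 + 0:(n_t - 1)
  tr <- schedule$trials
  nv <- schedule$n_videos; na <- schedule$n_sounds; nr <- schedule$n_repeats

  cnt <- table(factor(tr$video_id, levels = seq_len(nv)),
               factor(tr$sound_id, levels = seq_len(na)))
  if (any(cnt != nr)) {
    miss <- which(cnt < nr, arr.ind = TRUE)
    stop_arg("incomplete design; deficient (video, sound) pairs: ",
             paste(sprintf("(%d,%d)", miss[, 1], miss[, 2]), collapse = " "))
  }

  nc <- ncol(traces)
  if (is.null(channel_ids)) channel_ids <- colnames(traces)
  if (is.null(channel_ids)) channel_ids <- as.character(seq_len(nc))
  D <- array(NA_real_, dim = c(n_t, nv, na, nr, nc))
  t0 <- times[1]
  # order by onset so the repeat index within each pair follows presentation
  ord <- order(tr$onset)
  rep_count <- matrix(0L, nv, na)
  base_bins <- which(offsets < 0 & offsets >= round(-1 / bin_size))
  for (i in ord) {
    v <- tr$video_id[i]; a <- tr$sound_id[i]
    onset_bin <- floor((tr$onset[i] - t0) / bin_size) + 1L
    rows <- onset_bin + offsets
    if (rows[1] < 1L || rows[n_t] > nrow(traces))
      stop_arg("trial window falls outside the provided traces")
    rep_count[v, a] <- rep_count[v, a] + 1L
    seg <- traces[rows, , drop = FALSE]
    if (!is.null(baseline_channels) && length(base_bins)) {
      mu <- colMeans(seg[base_bins, baseline_channels, drop = FALSE])
      seg[, baseline_channels] <- sweep(seg[, baseline_channels, drop = FALSE],
                                        2, mu, "-")
    }
    D[, v, a, rep_count[v, a], ] <- seg
  }
  structure(D, class = "trial_tensor",
            bin_size = bin_size, window = window,
            rel_times = offsets * bin_size,
            channel_kind = channel_kind, channel_ids = channel_ids)
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Trial tensor [%s]: %d bins x %d videos x %d sounds x %d repeats x %d %ss\n",
              attr(x, "channel_kind"), d[1], d[2], d[3], d[4], d[5],
              attr(x, "channel_kind")))
  cat(sprintf("  window %.1f..%.1f s, bin %.0f ms\n", attr(x, "window")[1],
              attr(x, "window")[2], 1000 * attr(x, "bin_size")))
  invisible(x)
}

#' Preprocess a session into neural and behavioral trial tensors
#'
#' Runs the standard preprocessing chain on a synthetic (or equivalently
#' structured) session: spikes are binned at `bin_size`, smoothed with a
#' causal half-Gaussian (`sigma`), z-scored over the whole session and cut
#' into the neural trial tensor; motion PCs are linearly resampled to the
#' bin grid, z-scored, and combined with the 9 eye channels into the
#' behavioral trial tensor.
#'
#' @param session a [generate_session()] object (or [read_session()] list
#'   plus a `truth$n_neurons`-compatible `n_neurons`).
#' @param bin_size,sigma,window see [bin_and_zscore()] /
#'   [assemble_trial_tensor()].
#' @param n_motion_pcs number of motion PCs to carry (default: all).
#' @param n_neurons number of neurons (default: from the session's truth).
#' @return list with `neural` and `behavioral` trial tensors and `binned`
#'   (the continuous traces: `neural`, `eye`, `motion`, `times`).
#' @export
session_tensors <- function(session, bin_size = 0.030, sigma = 0.043,
                            window = c(-1, 3.8), n_motion_pcs = NULL,
                            n_neurons = session$truth$n_neurons) {
  t_end <- session$duration
  nb <- bin_and_zscore(session$spikes, n_neurons, bin_size, sigma,
                       t_start = 0, t_end = t_end)
  neural <- assemble_trial_tensor(nb$traces, nb$times, session$schedule,
                                  window = window, bin_size = bin_size,
                                  channel_kind = "neuron",
                                  channel_ids = paste0("n", seq_len(n_neurons)))
  eye_b <- bin_eye_channels(session$eye, bin_size, t_end)
  pcs <- session$motion$pcs
  if (!is.null(n_motion_pcs)) pcs <- pcs[, seq_len(n_motion_pcs), drop = FALSE]
  mot_b <- interp_columns(session$motion$times, pcs, eye_b$times + bin_size / 2)
  mot_b <- zscore_columns(mot_b, warn_label = "motion PC")
  eye_z <- eye_b$traces
  eye_z[, 1:8] <- zscore_columns(eye_z[, 1:8, drop = FALSE],
                                 warn_label = "eye channel")
  beh_traces <- cbind(eye_z, mot_b)
  colnames(beh_traces) <- c(colnames(eye_b$traces),
                            paste0("motion_pc", seq_len(ncol(mot_b))))
  behavioral <- assemble_trial_tensor(beh_traces, eye_b$times, session$schedule,
                                      window = window, bin_size = bin_size,
                                      channel_kind = "behavioral",
                                      channel_ids = colnames(beh_traces),
                                      baseline_channels = 1:3)
  list(neural = neural, behavioral = behavioral,
       binned = list(neural = nb$traces, eye = eye_b$traces,
                     motion = mot_b, times = nb$times, bin_size = bin_size))
}
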
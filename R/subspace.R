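# Movement-related neural subspace (reduced-rank regression on the
# spontaneous epoch), its overlap with the sound-related subspace, and
# movement-to-neural timing.

#' Lagged motion-PC design for the spontaneous epoch
#'
#' Expands a camera-rate motion-PC matrix into lagged copies: each PC
#' contributes `n_lags` columns at frame offsets `-(n_lags-1)/2 ..
#' +(n_lags-1)/2` (21 lags for 128 PCs gives 2,688 columns). Rows whose lag
#' span reaches outside the record are trimmed.
#'
#' @param motion frames x PCs matrix (spontaneous epoch, camera rate).
#' @param n_lags odd number of lags, centered on zero.
#' @return list: `values` (trimmed frames x PCs*n_lags), `lags` (frame
#'   offsets), `rows` (indices of retained frames in the input),
#'   `col_info`.
#' @export
build_lagged_motion <- function(motion, n_lags = 21) {
  motion <- as.matrix(motion)
  if (n_lags %% 2 == 0) stop_arg("n_lags must be odd (centered on zero)")
  L <- (n_lags - 1L) / 2L
  n <- nrow(motion)
  if (n <= 2L * L) stop_arg("epoch shorter than the lag span")
  rows <- (L + 1L):(n - L)
  p <- ncol(motion)
  X <- matrix(NA_real_, length(rows), p * n_lags)
  lags <- -L:L
  for (li in seq_along(lags)) {
    X[, (seq_len(p) - 1L) * n_lags + li] <- motion[rows - lags[li], , drop = FALSE]
  }
  list(values = X, lags = lags, rows = rows,
       col_info = data.frame(pc = rep(seq_len(p), each = n_lags),
                             lag = rep(lags, p)))
}

#' Reduced-rank regression of neural activity on lagged motion
#'
#' Fits `S ~ X B` with the coefficient matrix constrained to rank `r`, by
#' the classical two-step estimator: ordinary least squares, then truncation
#' of the fitted values to their top `r` singular structure. The
#' channel-space factor `C` (channels x r, orthonormal, ordered by the
#' variance of the fitted values it carries) is the movement-related neural
#' subspace. A small ridge penalty stabilizes the solve when the lagged
#' design is rank-deficient (recorded in the result).
#'
#' @param X lagged motion design (matrix, or a [build_lagged_motion()] list).
#' @param S frames x channels neural matrix (same rows as `X`).
#' @param rank the reduced rank (40 by default, matching the size used for
#'   the sound-related subspace comparison).
#' @param ridge optional explicit ridge penalty on the OLS step.
#' @return object of class `rrr_fit`: `C` (orthonormal basis), `L`
#'   (predictor-space factor so `B = L %*% t(C)`), `rank`, `singular_values`,
#'   centers, and `jitter` (any stabilization applied).
#' @export
fit_rrr <- function(X, S, rank = 40, ridge = 0) {
  if (is.list(X)) X <- X$values
  X <- as.matrix(X); S <- as.matrix(S)
  if (nrow(X) != nrow(S)) stop_arg("X and S row counts differ")
  if (rank > min(ncol(X), ncol(S))) stop_arg("rank exceeds matrix dimensions")
  xc <- colMeans(X); sc <- colMeans(S)
  Xc <- sweep(X, 2, xc, "-")
  Sc <- sweep(S, 2, sc, "-")
  XtX <- crossprod(Xc)
  XtS <- crossprod(Xc, Sc)
  jitter <- 0
  A <- XtX + diag(ridge, ncol(Xc))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-6 * mean(diag(XtX)) + 1e-12
    warning("rank-deficient design; ridge-stabilized solve (jitter = ",
            signif(jitter, 3), ")", call. = FALSE)
    ch <- chol(A + diag(jitter, ncol(Xc)))
  }
  B_ols <- backsolve(ch, forwardsolve(t(ch), XtS))
  Fhat <- Xc %*% B_ols
  sv <- svd(Fhat, nu = 0, nv = rank)
  C <- sv$v[, seq_len(rank), drop = FALSE]
  structure(list(C = C, L = B_ols %*% C, rank = rank,
                 singular_values = sv$d,
                 x_center = xc, s_center = sc,
                 ridge = ridge, jitter = jitter),
            class = "rrr_fit")
}

#' @export
print.rrr_fit <- function(x, ...) {
  cat(sprintf("Reduced-rank regression: rank %d, %d predictors -> %d channels\n",
              x$rank, nrow(x$L), nrow(x$C)))
  cat(sprintf("  top singular values of the fit: %s\n",
              paste(signif(x$singular_values[seq_len(min(4, length(x$singular_values)))], 3),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.rrr_fit <- function(object, ...) object$L %*% t(object$C)

# Per-dimension test-retest covariance of two half components projected on
# an orthonormal basis Q.
projected_covariance <- function(mat_train, mat_test, Q) {
  Ttr <- mat_train %*% Q
  Tte <- mat_test %*% Q
  Ttr <- sweep(Ttr, 2, colMeans(Ttr), "-")
  Tte <- sweep(Tte, 2, colMeans(Tte), "-")
  colSums(Ttr * Tte) / (nrow(Ttr) - 1)
}

#' Overlap of the movement-related and sound-related subspaces
#'
#' Projects the train- and test-half sound-related activity onto the
#' movement-related basis `C` and measures the test-retest covariance along
#' each dimension (the same estimator cvPCA uses, but along
#' behavior-defined directions). The overlap is the ratio of the reliable
#' sound-related variance captured by the first `k` movement dimensions to
#' that captured by the first `k` auditory PCs themselves. A reference
#' distribution is obtained from random k-dimensional subspaces
#' (orthonormalized Gaussian draws); the 95th percentile of their overlap is
#' the chance threshold. The ratio is reported as computed — noise can push
#' it above 1 and the per-dimension covariances can be negative.
#'
#' @param comp_train,comp_test train/test-half sound-related components
#'   (arrays `[t, a, c]`).
#' @param C orthonormal channel basis from [fit_rrr()].
#' @param k number of leading dimensions compared (4).
#' @param auditory_vhat the auditory cvPCA covariances (numeric vector or a
#'   [cvpca_spectrum()] object) — the denominator's first `k` entries.
#' @param n_random random subspaces for the chance threshold (>= 100).
#' @param seed integer seed for the random subspaces.
#' @return object of class `overlap_result`: `variance_along` (per
#'   dimension of `C`), `overlap_ratio`, `random_threshold`,
#'   `random_ratios`, `k`.
#' @export
subspace_overlap <- function(comp_train, comp_test, C, k = 4,
                             auditory_vhat, n_random = 200, seed = NULL) {
  if (inherits(auditory_vhat, "cvpca")) auditory_vhat <- auditory_vhat$vhat
  mat_tr <- flatten_component(comp_train)
  mat_te <- flatten_component(comp_test)
  nc <- ncol(mat_tr)
  if (k > ncol(C) || k > length(auditory_vhat))
    stop_arg("k exceeds the available dimensions")
  if (n_random < 100) stop_arg("n_random must be >= 100")
  ortho <- crossprod(C)
  if (max(abs(ortho - diag(ncol(C)))) > 1e-6)
    stop_arg("C is not orthonormal")
  var_along <- projected_covariance(mat_tr, mat_te, C)
  denom <- sum(auditory_vhat[seq_len(k)])
  ratio <- sum(var_along[seq_len(k)]) / denom
  rand <- with_seed(seed, vapply(seq_len(n_random), function(i) {
    Q <- qr.Q(qr(matrix(stats::rnorm(nc * k), nc, k)))
    sum(projected_covariance(mat_tr, mat_te, Q)) / denom
  }, 0))
  structure(list(variance_along = var_along, overlap_ratio = ratio,
                 random_threshold = stats::quantile(rand, 0.95, names = FALSE),
                 random_ratios = rand, k = k),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Subspace overlap (first %d dimensions): %.1f%% of the sound-related variance\n",
              x$k, 100 * x$overlap_ratio))
  cat(sprintf("  random-subspace 95th percentile: %.1f%%\n",
              100 * x$random_threshold))
  invisible(x)
}

#' Cross-correlogram lag between movement and neural activity
#'
#' Normalized cross-correlation of two uniformly sampled series over lags up
#' to `max_lag` seconds, and the lag of its peak. Positive lags mean the
#' first series (movement) precedes the second (neural activity).
#'
#' @param x movement series (e.g. motion PC1 during the spontaneous epoch).
#' @param y neural series (e.g. auditory PC1 at the camera rate).
#' @param rate common sampling rate, Hz.
#' @param max_lag correlogram half-width, seconds.
#' @return object of class `xcorr_lag`: `lag` (seconds, at the peak),
#'   `peak` (correlation there), `lags`, `correlogram`.
#' @export
xcorr_lag <- function(x, y, rate, max_lag = 2) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_arg("series lengths differ")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_arg("constant series: cross-correlogram undefined")
  L <- round(max_lag * rate)
  n <- length(x)
  if (n <= L + 2) stop_arg("series too short for the requested max_lag")
  lags <- -L:L
  cc <- vapply(lags, function(l) {
    if (l >= 0) stats::cor(x[seq_len(n - l)], y[seq_len(n - l) + l])
    else stats::cor(x[seq_len(n + l) - l], y[seq_len(n + l)])
  }, 0)
  best <- which.max(cc)
  structure(list(lag = lags[best] / rate, peak = cc[best],
                 lags = lags / rate, correlogram = cc, rate = rate),
            class = "xcorr_lag")
}

#' @export
print.xcorr_lag <- function(x, ...) {
  cat(sprintf("Cross-correlogram peak r = %.2f at lag %+.0f ms (positive: movement precedes)\n",
              x$peak, 1000 * x$lag))
  invisible(x)
}

#' @export
plot.xcorr_lag <- function(x, ...) {
  graphics::plot(x$lags, x$correlogram, type = "l",
                 xlab = "lag (s, + = movement precedes)",
                 ylab = "correlation", ...)
  graphics::abline(v = x$lag, lty = 2)
  invisible(x)
}

#' Peak lag of a predictor's regression weights
#'
#' Given ridge weights of one motion PC across lags (from a lagged
#' regression of neural activity on motion), returns the lag (seconds) at
#' which the absolute weight peaks — the delay at which movement best
#' predicts activity. Positive values mean movement precedes.
#'
#' @param weights numeric vector of weights, one per lag.
#' @param lags frame offsets matching `weights` (positive = movement
#'   earlier).
#' @param rate sampling rate, Hz.
#' @return peak delay in seconds (NA with a warning if the weights are flat).
#' @export
weight_peak_delay <- function(weights, lags, rate) {
  if (length(weights) != length(lags)) stop_arg("weights and lags differ in length")
  if (max(abs(weights)) < 1e-12 || diff(range(weights)) < 1e-12) {
    warning("flat weight profile; delay undefined", call. = FALSE)
    return(NA_real_)
  }
  lags[which.max(abs(weights))] / rate
}

#' Movement-to-neural timing during the spontaneous epoch
#'
#' Convenience wrapper computing both timing measures on a session's
#' spontaneous epoch, at the camera frame rate: (1) the cross-correlogram
#' lag between motion PC1 and the first auditory PC (neurons binned at the
#' camera rate, z-scored, projected on `w_neural`), and (2) the peak lag of
#' motion PC1's weights in a ridge regression of that component on the
#' lagged motion PCs (the regression route is robust to autocorrelation in
#' the two series).
#'
#' @param session a [generate_session()] object.
#' @param w_neural channel weights of the neural component to track
#'   (e.g. first column of [component_pcs()] from the full-data sound
#'   component).
#' @param n_motion_pcs motion PCs entering the lagged regression.
#' @param n_lags lags in the regression design (odd, centered).
#' @param lambda_grid ridge penalties searched by 3-fold contiguous CV.
#' @param max_lag correlogram half-width, seconds.
#' @return list: `xcorr` (an `xcorr_lag`), `xcorr_lag_s`, `weight_delay_s`,
#'   `pc1_weights` (per lag), `lags_s`.
#' @export
spontaneous_timing <- function(session, w_neural, n_motion_pcs = NULL,
                               n_lags = 21, lambda_grid = 10^seq(-2, 4),
                               max_lag = 2) {
  ep <- session$schedule$spontaneous_epoch
  rate <- session$motion$rate
  nb <- bin_and_zscore(session$spikes, length(w_neural),
                       bin_size = 1 / rate, sigma = NULL,
                       t_start = 0, t_end = session$duration, zscore = FALSE)
  bsel <- nb$times >= ep[1] & nb$times <= ep[2]
  S <- zscore_columns(nb$traces[bsel, , drop = FALSE], warn_label = "neuron")
  # spike counts integrate over each bin, so compare motion sampled at the
  # bin centers — point samples at the bin edges would bias the lag by half
  # a frame
  centers <- nb$times[bsel] + 0.5 / rate
  pcs <- session$motion$pcs
  if (!is.null(n_motion_pcs)) pcs <- pcs[, seq_len(n_motion_pcs), drop = FALSE]
  mot <- interp_columns(session$motion$times, pcs, centers)
  mot <- zscore_columns(mot, warn_label = "motion PC")
  pc1 <- as.numeric(S %*% w_neural)

  xc <- xcorr_lag(mot[, 1], pc1, rate, max_lag = max_lag)

  lag_des <- build_lagged_motion(mot, n_lags)
  yl <- pc1[lag_des$rows]
  # 3-fold contiguous ridge CV on plain matrices
  n <- length(yl)
  fold <- cut(seq_len(n), 3, labels = FALSE)
  XtX <- crossprod(lag_des$values)
  Xty <- crossprod(lag_des$values, yl)
  sse <- vapply(lambda_grid, function(lam) {
    s <- 0
    for (f in 1:3) {
      inf <- fold == f
      Xf <- lag_des$values[!inf, , drop = FALSE]
      b <- ridge_solve(crossprod(Xf), crossprod(Xf, yl[!inf]), lam)
      s <- s + sum((yl[inf] - lag_des$values[inf, , drop = FALSE] %*% b)^2)
    }
    s
  }, 0)
  b <- ridge_solve(XtX, Xty, lambda_grid[which.min(sse)])
  pc1_w <- b[lag_des$col_info$pc == 1]
  names(pc1_w) <- lag_des$lags
  list(xcorr = xc, xcorr_lag_s = xc$lag,
       weight_delay_s = weight_peak_delay(pc1_w, lag_des$lags, rate),
       pc1_weights = pc1_w, lags_s = lag_des$lags / rate)
}
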
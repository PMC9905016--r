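# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards. seed = NULL uses (and advances) the
# current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one parent seed (kept < 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.integer((as.numeric(seed) * 1009 + 7919 * seq_len(n)) %% 2147483629)
}

stop_arg <- function(...) stop(..., call. = FALSE)

# Gaussian low-pass smoothing of the columns of a matrix (symmetric kernel),
# used for slow latent fluctuations and smooth visual time courses.
smooth_gaussian <- function(x, sigma_bins) {
  x <- as.matrix(x)
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  n <- nrow(x)
  pad <- matrix(0, half, ncol(x))
  f <- stats::filter(rbind(pad, x, pad), k, sides = 2)
  out <- as.matrix(f)[half + seq_len(n), , drop = FALSE]
  # correct edge attenuation so a constant input stays constant
  if (n > 2L * half) {
    w <- rep(1, n)
    cs <- cumsum(k)
    e <- seq_len(half)
    w[e] <- cs[half + e]
    w[n + 1L - e] <- cs[half + e]
  } else {
    w <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
    w <- as.numeric(w)[half + seq_len(n)]
  }
  out / w
}

# Linear interpolation of each column of `values` (sampled at `times`)
# onto `at`; constant extrapolation at the edges.
interp_columns <- function(times, values, at) {
  values <- as.matrix(values)
  out <- matrix(NA_real_, length(at), ncol(values))
  for (j in seq_len(ncol(values))) {
    out[, j] <- stats::approx(times, values[, j], xout = at, rule = 2)$y
  }
  colnames(out) <- colnames(values)
  out
}

# z-score columns; zero-variance columns become all zeros with a warning.
zscore_columns <- function(x, warn_label = "channel") {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad)) {
    warning(sum(bad), " ", warn_label, "(s) with zero variance; returning zeros",
            call. = FALSE)
    sdv[bad] <- 1
    mu[bad] <- x[1, bad]
  }
  out <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

# Pearson correlation of two vectors over finite pairs; NA (with optional
# warning) when either side has no variance.
safe_cor <- function(a, b, warn = FALSE) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) {
    if (warn) warning("correlation undefined (constant input)", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}
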
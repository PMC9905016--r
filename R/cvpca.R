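#' Odd/even repeat split
#'
#' The standard cross-validation split: odd-numbered repeats form the
#' training half, even-numbered repeats the test half. Because every
#' (video, sound) pair appears once per repeat, both halves are balanced
#' across the design.
#'
#' @param n_repeats number of repeats in the tensor.
#' @return list with integer vectors `train` and `test`.
#' @export
repeat_split <- function(n_repeats) {
  if (n_repeats < 2) stop_arg("need at least 2 repeats to split")
  list(train = seq(1, n_repeats, by = 2), test = seq(2, n_repeats, by = 2))
}

# Flatten a marginal component [t, stim..., c] to (t * stim) x channels.
flatten_component <- function(comp) {
  d <- dim(comp)
  matrix(comp, prod(d[-length(d)]), d[length(d)])
}

# Minimal cvPCA: eigendecompose the train matrix, project both halves, and
# return the per-component test-retest covariance. Used in the shuffle loop.
# Works from channel-space moments; marginal components are exactly
# zero-mean across their own stimulus index, so no centering is needed.
cvpca_core <- function(mat_train, mat_test, n_components) {
  n <- nrow(mat_train)
  C11 <- crossprod(mat_train)
  C12 <- crossprod(mat_train, mat_test)
  ee <- eigen(C11, symmetric = TRUE)
  W <- ee$vectors[, seq_len(n_components), drop = FALSE]
  colSums(W * (C12 %*% W)) / (n - 1)
}

#' Cross-validated PCA signal-variance spectrum
#'
#' Estimates the reliable (stimulus-locked) variance along each principal
#' component of a trial-averaged marginal component. PCA weights `W` are
#' computed from the training-half component; both halves are projected with
#' the same `W`, and the per-component covariance between train and test
#' projections is an unbiased estimate of that component's signal variance —
#' independent noise averages to zero in the cross-covariance, so estimates
#' for noise dimensions scatter around zero and may legitimately be negative
#' (they are not clipped).
#'
#' Each weight column is sign-fixed so its mean channel weight is
#' non-negative (PC signs are otherwise arbitrary; population weights on the
#' first sound component are reported with a positive bias in vivo).
#'
#' @param comp_train,comp_test the same marginal component (e.g. the
#'   sound-related array `[t, a, c]`) computed from the train and test halves.
#' @param n_components number of components to keep; default: all channels
#'   (the full spectrum).
#' @return object of class `cvpca`: `W` (channels x components),
#'   `proj_train`/`proj_test` (row space (t * stim) x components), `vhat`
#'   (test-retest covariance per component), `train_variance`,
#'   `normalized_spectrum` (`vhat / sum(vhat)`), `stim_dims`.
#' @export
cvpca_spectrum <- function(comp_train, comp_test, n_components = NULL) {
  if (!identical(dim(comp_train), dim(comp_test)))
    stop_arg("train and test components must have identical shape")
  d <- dim(comp_train)
  nc <- d[length(d)]
  mat_tr <- flatten_component(comp_train)
  mat_te <- flatten_component(comp_test)
  np <- if (is.null(n_components)) min(nc, nrow(mat_tr)) else n_components
  if (np > nc) stop_arg("n_components exceeds the number of channels")

  ee <- eigen(crossprod(mat_tr), symmetric = TRUE)
  W <- ee$vectors[, seq_len(np), drop = FALSE]
  flip <- colMeans(W) < 0
  W[, flip] <- -W[, flip]
  Ttr <- mat_tr %*% W
  Tte <- mat_te %*% W
  ctr <- sweep(Ttr, 2, colMeans(Ttr), "-")
  cte <- sweep(Tte, 2, colMeans(Tte), "-")
  n <- nrow(Ttr)
  vhat <- colSums(ctr * cte) / (n - 1)
  structure(list(
    W = W, proj_train = Ttr, proj_test = Tte,
    vhat = vhat,
    train_variance = colSums(ctr^2) / (n - 1),
    normalized_spectrum = vhat / sum(vhat),
    n_components = np, n_rows = n,
    stim_dims = d[-length(d)],
    channel_ids = attr(comp_train, "channel_ids")
  ), class = "cvpca")
}

#' @export
print.cvpca <- function(x, ...) {
  cat(sprintf("cvPCA: %d components over %d rows\n", x$n_components, x$n_rows))
  k <- min(5, x$n_components)
  cat("  top test-retest covariances:",
      paste(sprintf("%.3g", x$vhat[seq_len(k)]), collapse = ", "), "\n")
  cat(sprintf("  component 1 share of summed covariance: %.1f%%\n",
              100 * x$vhat[1] / sum(x$vhat)))
  invisible(x)
}

#' @export
plot.cvpca <- function(x, n = min(30, x$n_components), normalized = TRUE, ...) {
  y <- if (normalized) x$normalized_spectrum else x$vhat
  graphics::plot(seq_len(n), y[seq_len(n)], log = "x", type = "b", pch = 16,
                 xlab = "component", ylab = if (normalized)
                   "fraction of summed signal variance" else
                     "test-retest covariance", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Signed time course of one principal component
#'
#' Reshapes a component's projection back to a time x stimulus matrix. The
#' weights always come from the training half; the projected data can be the
#' train half, the test half, or the full dataset (the average of the two
#' balanced halves), which is the convention used for displaying component
#' time courses.
#'
#' @param result a [cvpca_spectrum()] object.
#' @param component_index which component.
#' @param data `"full"`, `"train"` or `"test"`.
#' @return matrix (time bins x stimuli) in arbitrary (signed) units.
#' @export
pc_timecourse <- function(result, component_index = 1,
                          data = c("full", "train", "test")) {
  data <- match.arg(data)
  if (component_index > result$n_components) stop_arg("component_index too large")
  proj <- switch(data,
                 train = result$proj_train[, component_index],
                 test = result$proj_test[, component_index],
                 full = (result$proj_train[, component_index] +
                           result$proj_test[, component_index]) / 2)
  matrix(proj, result$stim_dims[1], prod(result$stim_dims[-1]))
}

#' Fisher-z average of correlation coefficients
#'
#' Averages correlations through the variance-stabilizing arctanh transform:
#' `tanh(mean(atanh(r)))`. Coefficients with `|r| = 1` (infinite z) are
#' excluded with a warning; `NA` values are dropped.
#'
#' @param r numeric vector of correlation coefficients.
#' @return the back-transformed mean correlation.
#' @export
fisher_mean_correlation <- function(r) {
  r <- r[!is.na(r)]
  bad <- abs(r) >= 1
  if (any(bad)) {
    warning(sum(bad), " coefficient(s) with |r| = 1 excluded", call. = FALSE)
    r <- r[!bad]
  }
  if (!length(r)) return(NA_real_)
  tanh(mean(atanh(r)))
}

#' Shuffle test for the dimensionality of a marginal component
#'
#' Tests which cvPCA components of the video-, sound- or interaction-related
#' activity carry variance significantly above chance. The null is built by
#' relabeling: within every repeat, the (video, sound) label pairs of the
#' trials are randomly permuted — changing both the video and the sound
#' label of each trial — the marginal component and its cvPCA test-retest
#' covariances are recomputed, and this is repeated `n_shuffles` times. A
#' component is significant when its observed covariance exceeds the 99th
#' percentile (strictly) of the shuffled distribution; the dimensionality of
#' the component is the number of significant components.
#'
#' By default the threshold comes from the pooled distribution of shuffled
#' covariance values across all components (`null_type = "pooled"`). Because
#' the relabeling breaks the balance of the factorial design, the strong
#' stimulus-related signal bleeds into the shuffled components and the
#' pooled 99th percentile sits far above the noise floor, making the test
#' conservative — consistent with the zero interaction dimensionality
#' observed on real recordings even with hundreds of neurons.
#' `null_type = "per_component"` compares each component against its own
#' shuffled distribution instead; that variant is close to exact per
#' component, so with many channels a ~1% false-positive rate per component
#' accumulates into occasional spurious dimensions.
#'
#' @param D a neural (or behavioral) `trial_tensor`.
#' @param component_kind `"video"`, `"sound"` or `"interaction"`.
#' @param n_shuffles number of relabelings (>= 100).
#' @param percentile null percentile defining significance (per cent).
#' @param n_components how many components to test (default: all channels).
#' @param null_type `"pooled"` (one null distribution over all components)
#'   or `"per_component"`.
#' @param seed integer seed for the relabelings.
#' @return object of class `shuffle_test`: `vhat` (observed), `threshold`,
#'   `significant` (logical mask), `n_significant`, `null` (shuffles x
#'   components matrix).
#' @export
shuffle_significance <- function(D, component_kind = c("sound", "video", "interaction"),
                                 n_shuffles = 1000, percentile = 99,
                                 n_components = NULL,
                                 null_type = c("pooled", "per_component"),
                                 seed = NULL) {
  component_kind <- match.arg(component_kind)
  null_type <- match.arg(null_type)
  if (n_shuffles < 100) stop_arg("n_shuffles must be >= 100")
  d <- dim(D)
  nt <- d[1]; nv <- d[2]; na <- d[3]; nr <- d[4]; nc <- d[5]
  if (nr < 2) stop_arg("need >= 2 repeats for the train/test split")
  np <- if (is.null(n_components)) nc else n_components
  if (np > nc) stop_arg("n_components exceeds the number of channels")
  split <- repeat_split(nr)

  # degenerate single-stimulus design: nothing to relabel
  if ((component_kind == "sound" && na < 2) ||
      (component_kind == "video" && nv < 2) ||
      (component_kind == "interaction" && (nv < 2 || na < 2))) {
    return(structure(list(vhat = rep(NA_real_, np),
                          threshold = rep(NA_real_, np),
                          significant = rep(FALSE, np), n_significant = 0L,
                          null = NULL, component_kind = component_kind,
                          n_shuffles = 0L, percentile = percentile),
                     class = "shuffle_test"))
  }

  Dm <- unclass(D)
  npair <- nv * na
  # pair-major view of each repeat: [pair, t * c]
  Sp <- lapply(seq_len(nr), function(r) {
    s <- array(Dm[, , , r, ], dim = c(nt, npair, nc))
    matrix(aperm(s, c(2, 1, 3)), npair, nt * nc)
  })
  v_of_pair <- rep(seq_len(nv), na)
  a_of_pair <- rep(seq_len(na), each = nv)
  M_of <- function(reps) {
    m <- 0
    for (r in reps) m <- m + colMeans(Sp[[r]])
    matrix(m / length(reps), nt, nc)
  }
  M_half <- list(train = M_of(split$train), test = M_of(split$test))

  # marginal component of one half under per-repeat pair-label permutations
  half_comp <- function(reps, perms, M) {
    nrep <- length(reps)
    if (component_kind == "sound") {
      acc <- 0
      for (i in seq_len(nrep)) {
        G <- matrix(0, na, npair)
        G[cbind(a_of_pair, perms[[i]])] <- 1 / nv
        acc <- acc + G %*% Sp[[reps[i]]]
      }
      arr <- aperm(array(acc / nrep, dim = c(na, nt, nc)), c(2, 1, 3))
      for (a in seq_len(na)) arr[, a, ] <- arr[, a, ] - M
      matrix(arr, nt * na, nc)
    } else if (component_kind == "video") {
      acc <- 0
      for (i in seq_len(nrep)) {
        G <- matrix(0, nv, npair)
        G[cbind(v_of_pair, perms[[i]])] <- 1 / na
        acc <- acc + G %*% Sp[[reps[i]]]
      }
      arr <- aperm(array(acc / nrep, dim = c(nv, nt, nc)), c(2, 1, 3))
      for (v in seq_len(nv)) arr[, v, ] <- arr[, v, ] - M
      matrix(arr, nt * nv, nc)
    } else {
      P <- 0
      Aacc <- 0
      Vacc <- 0
      for (i in seq_len(nrep)) {
        P <- P + Sp[[reps[i]]][perms[[i]], , drop = FALSE]
        Ga <- matrix(0, na, npair)
        Ga[cbind(a_of_pair, perms[[i]])] <- 1 / nv
        Gv <- matrix(0, nv, npair)
        Gv[cbind(v_of_pair, perms[[i]])] <- 1 / na
        Aacc <- Aacc + Ga %*% Sp[[reps[i]]]
        Vacc <- Vacc + Gv %*% Sp[[reps[i]]]
      }
      # I = P - A - V + M, all in the pair-major layout
      Ip <- (P - Aacc[a_of_pair, , drop = FALSE] -
               Vacc[v_of_pair, , drop = FALSE]) / nrep
      Ip <- Ip + matrix(as.numeric(M), npair, nt * nc, byrow = TRUE)
      matrix(aperm(array(Ip, dim = c(npair, nt, nc)), c(2, 1, 3)),
             nt * nv * na, nc)
    }
  }

  id <- rep(list(seq_len(npair)), nr)
  vhat_obs <- cvpca_core(half_comp(split$train, id[split$train], M_half$train),
                         half_comp(split$test, id[split$test], M_half$test), np)

  null <- with_seed(seed, {
    out <- matrix(NA_real_, n_shuffles, np)
    for (s in seq_len(n_shuffles)) {
      perms <- lapply(seq_len(nr), function(r) sample.int(npair))
      out[s, ] <- cvpca_core(half_comp(split$train, perms[split$train],
                                       M_half$train),
                             half_comp(split$test, perms[split$test],
                                       M_half$test), np)
    }
    out
  })
  threshold <- if (null_type == "pooled")
    rep(stats::quantile(as.vector(null), probs = percentile / 100,
                        names = FALSE), np)
  else
    apply(null, 2, stats::quantile, probs = percentile / 100, names = FALSE)
  significant <- vhat_obs > threshold
  structure(list(vhat = vhat_obs, threshold = threshold,
                 significant = significant,
                 n_significant = sum(significant),
                 null = null, component_kind = component_kind,
                 n_shuffles = n_shuffles, percentile = percentile,
                 null_type = null_type),
            class = "shuffle_test")
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat(sprintf("Shuffle test (%s component): %d of %d components significant\n",
              x$component_kind, x$n_significant, length(x$vhat)))
  cat(sprintf("  %d relabelings, %gth percentile threshold\n",
              x$n_shuffles, x$percentile))
  invisible(x)
}
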
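#' Template-matching stimulus decoder
#'
#' Decodes the sound (or video) presented on each test trial from a trial
#' tensor. For sound decoding: the mean training-set response to the trial's
#' video is subtracted from the trial (removing the video-related
#' component), the residual time course is projected onto the top
#' `n_components` PCs of the training-half sound-related activity, and the
#' trial is assigned to the sound whose training-set mean projected time
#' course is nearest in Euclidean distance (whole time courses are compared,
#' flattened over time and components). Video decoding is the symmetric
#' procedure (per-sound train mean subtracted, video-marginal PCs). Ties are
#' broken toward the lowest stimulus index, so decoding is deterministic.
#'
#' Both halves of the balanced split contain equally many trials of each
#' stimulus, so chance accuracy is `1 / n_classes`.
#'
#' @param D a `trial_tensor` (neural or behavioral).
#' @param target `"sound"` or `"video"`.
#' @param split a [repeat_split()]; which repeats are train vs test.
#' @param n_components number of training-half PCs used (4 for sound
#'   decoding; 30 for video decoding in cortex).
#' @return object of class `decode_result`: `accuracy`, `confusion`
#'   (true x decoded counts), `decoded`, `truth`, `n_components`,
#'   `chance_level`.
#' @export
template_decode <- function(D, target = c("sound", "video"),
                            split = repeat_split(dim(D)[4]),
                            n_components = if (match.arg(target) == "sound") 4 else 30) {
  target <- match.arg(target)
  d <- dim(D)
  nt <- d[1]; nv <- d[2]; na <- d[3]; nc <- d[5]
  if (n_components > nc) stop_arg("n_components exceeds the number of channels")
  Dm <- unclass(D)

  # training-half averages
  ntr_reps <- length(split$train)
  Ptr <- 0
  for (r in split$train)
    Ptr <- Ptr + array(Dm[, , , r, ], dim = c(nt, nv, na, nc))
  Ptr <- Ptr / ntr_reps
  Vmean <- colMeans(aperm(Ptr, c(3, 1, 2, 4)), dims = 1)   # [t, v, c]
  Amean <- colMeans(aperm(Ptr, c(2, 1, 3, 4)), dims = 1)   # [t, a, c]
  M <- colMeans(aperm(Amean, c(2, 1, 3)), dims = 1)        # [t, c]

  if (target == "sound") {
    marg <- Amean
    for (a in seq_len(na)) marg[, a, ] <- marg[, a, ] - M
    sub_mean <- Vmean                  # subtracted per trial, by video
    n_class <- na
  } else {
    marg <- Vmean
    for (v in seq_len(nv)) marg[, v, ] <- marg[, v, ] - M
    sub_mean <- Amean                  # subtracted per trial, by sound
    n_class <- nv
  }

  mat <- matrix(marg, nt * n_class, nc)
  ee <- eigen(crossprod(mat), symmetric = TRUE)
  W <- ee$vectors[, seq_len(n_components), drop = FALSE]
  flip <- colMeans(W) < 0
  W[, flip] <- -W[, flip]
  templ <- array(mat %*% W, dim = c(nt, n_class, n_components))
  templ_feat <- matrix(aperm(templ, c(2, 1, 3)), n_class, nt * n_components)

  # test trials, condition mean removed
  nte <- length(split$test)
  Dte <- array(Dm[, , , split$test, ], dim = c(nt, nv, na, nte, nc))
  for (v in seq_len(nv)) for (a in seq_len(na)) {
    sub <- if (target == "sound") sub_mean[, v, ] else sub_mean[, a, ]
    for (r in seq_len(nte)) Dte[, v, a, r, ] <- Dte[, v, a, r, ] - sub
  }
  proj <- array(matrix(Dte, nt * nv * na * nte, nc) %*% W,
                dim = c(nt, nv, na, nte, n_components))
  feat <- matrix(aperm(proj, c(2, 3, 4, 1, 5)), nv * na * nte,
                 nt * n_components)
  d2 <- outer(rowSums(feat^2), rowSums(templ_feat^2), "+") -
    2 * feat %*% t(templ_feat)
  decoded <- max.col(-d2, ties.method = "first")
  truth <- if (target == "sound")
    rep(rep(seq_len(na), each = nv), nte)
  else
    rep(seq_len(nv), na * nte)
  confusion <- table(true = factor(truth, seq_len(n_class)),
                     decoded = factor(decoded, seq_len(n_class)))
  structure(list(accuracy = mean(decoded == truth),
                 confusion = unclass(confusion),
                 decoded = decoded, truth = truth,
                 n_components = n_components,
                 chance_level = 1 / n_class,
                 target = target),
            class = "decode_result")
}

#' Decode stimulus identity from behavioral channels
#'
#' Runs the template-matching decoder on a behavioral trial tensor (eye
#' channels and/or facial motion-energy PCs), exactly as for neural data.
#' When the tensor has no more channels than `n_components`, all channels
#' are used directly (projection onto all PCs is an isometry, so this is
#' equivalent).
#'
#' @inheritParams template_decode
#' @param B behavioral `trial_tensor`.
#' @return a `decode_result`.
#' @export
behavioral_decode <- function(B, target = c("sound", "video"),
                              split = repeat_split(dim(B)[4]),
                              n_components = 4) {
  template_decode(B, target, split, min(n_components, dim(B)[5]))
}

#' Relabel stimuli within each repeat
#'
#' Permutes the sound (or video) labels of a trial tensor independently
#' within each repeat, preserving the balanced design while destroying the
#' association between label and response. Used to establish chance-level
#' decoding.
#'
#' @param D a `trial_tensor`.
#' @param target which labels to permute.
#' @param seed integer seed.
#' @return the relabeled `trial_tensor`.
#' @export
permute_labels <- function(D, target = c("sound", "video"), seed = NULL) {
  target <- match.arg(target)
  d <- dim(D)
  out <- unclass(D)
  with_seed(seed, {
    for (r in seq_len(d[4])) {
      if (target == "sound")
        out[, , , r, ] <- out[, , sample.int(d[3]), r, ]
      else
        out[, , , r, ] <- out[, sample.int(d[2]), , r, ]
    }
  })
  attributes(out) <- attributes(D)
  out
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("Template decoding of %s identity: accuracy %.1f%% (chance %.1f%%)\n",
              x$target, 100 * x$accuracy, 100 * x$chance_level))
  cat(sprintf("  %d components, %d test trials\n",
              x$n_components, length(x$decoded)))
  invisible(x)
}

#' @export
plot.decode_result <- function(x, ...) {
  cf <- x$confusion / rowSums(x$confusion)
  graphics::image(seq_len(ncol(cf)), seq_len(nrow(cf)), t(cf)[, rev(seq_len(nrow(cf)))],
                  xlab = "decoded", ylab = "true", main = sprintf(
                    "%s decoding, accuracy %.1f%%", x$target, 100 * x$accuracy),
                  ...)
  invisible(x)
}
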
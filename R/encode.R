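# Encoding models: predict single-trial sound-related activity (in the
# auditory PC basis) from stimulus identity and/or lagged behavioral
# channels, with ridge regression.

# Canonical row layout of the encoding matrices: trials ordered video-fastest
# then sound then repeat; each trial contributes `pad` NA rows, `n_t_enc`
# in-trial rows, `pad` NA rows. The NA pads stop temporal filters from
# predicting across trial boundaries.
encoding_rows <- function(n_t_enc, pad, n_trials) {
  per <- n_t_enc + 2L * pad
  list(trial = rep(seq_len(n_trials), each = per),
       bin = rep(c(rep(NA_integer_, pad), seq_len(n_t_enc),
                   rep(NA_integer_, pad)), n_trials),
       per_trial = per)
}

# Indices of the tensor time bins used for encoding: the bins at or after
# stimulus onset (127 bins for the (-1, 3.8) s window at 30 ms).
encoding_bins <- function(tensor) which(attr(tensor, "rel_times") >= -1e-9)

#' Build an encoding-model design matrix
#'
#' Constructs the predictor matrix for the three encoding models.
#' * `"auditory"`: one indicator column per (sound, peristimulus bin)
#'   combination — `n_sounds * n_t_enc` columns (1,524 for 12 sounds and 127
#'   bins); every in-trial row has exactly one 1 among its sound's columns.
#'   Fitting this model is equivalent to estimating the train-half mean time
#'   course per sound.
#' * `"behavioral"`: the sound-related single-trial behavioral channels
#'   (tensor minus its grand mean and video component) at `length(lags)`
#'   temporal offsets — `n_channels * n_lags` columns (137 channels x 12
#'   lags = 1,644). The lag grid spans -90 to +240 ms at 30 ms bins;
#'   positive lags let earlier behavior predict later activity.
#' * `"full"`: the horizontal concatenation of the two (3,168 columns).
#'
#' Rows follow [encoding_rows()]: `(n_t_enc + 2 * pad)` rows per trial with
#' `pad` all-NA rows at each trial edge; behavioral columns are additionally
#' NA where a lag reaches outside the trial window.
#'
#' @param kind `"auditory"`, `"behavioral"` or `"full"`.
#' @param tensor the neural `trial_tensor` (defines the design dimensions).
#' @param behavior the behavioral `trial_tensor` (required unless
#'   `kind = "auditory"`).
#' @param behavior_marg optional precomputed [marginalize()] of `behavior`.
#' @param lags integer bin offsets for the behavioral predictors.
#' @param pad NA rows at each trial edge (defaults to the number of lags).
#' @return object of class `design_matrix`: `values`, `col_info`, the row
#'   layout (`trial`, `bin`, `trial_meta`), `lags`, `pad`, `n_t_enc`.
#' @export
build_design <- function(kind = c("auditory", "behavioral", "full"),
                         tensor, behavior = NULL, behavior_marg = NULL,
                         lags = -3:8, pad = length(lags)) {
  kind <- match.arg(kind)
  d <- dim(tensor)
  nv <- d[2]; na <- d[3]; nr <- d[4]
  enc <- encoding_bins(tensor)
  nte <- length(enc)
  if (max(abs(lags)) > pad) stop_arg("lag span exceeds the pad length")
  ntrials <- nv * na * nr
  rows <- encoding_rows(nte, pad, ntrials)
  n_rows <- length(rows$trial)
  trial_meta <- expand.grid(v = seq_len(nv), a = seq_len(na), r = seq_len(nr))

  make_aud <- function() {
    X <- matrix(NA_real_, n_rows, na * nte)
    ok <- !is.na(rows$bin)
    X[ok, ] <- 0
    cols <- (trial_meta$a[rows$trial[ok]] - 1L) * nte + rows$bin[ok]
    X[cbind(which(ok), cols)] <- 1
    info <- data.frame(kind = "stimulus",
                       id = rep(seq_len(na), each = nte),
                       offset = rep(seq_len(nte), na))
    list(X = X, info = info)
  }
  make_beh <- function() {
    if (is.null(behavior)) stop_arg("behavioral tensor required")
    if (is.null(behavior_marg)) behavior_marg <- marginalize(behavior)
    nch <- dim(behavior)[5]
    Bm <- single_trial_component(behavior, behavior_marg, enc)   # [nte, ntr, ch]
    nlag <- length(lags)
    X <- matrix(NA_real_, n_rows, nch * nlag)
    ok <- which(!is.na(rows$bin))
    for (li in seq_along(lags)) {
      lg <- lags[li]
      shifted <- array(NA_real_, dim = dim(Bm))
      dest <- seq_len(nte)[seq_len(nte) - lg >= 1 & seq_len(nte) - lg <= nte]
      shifted[dest, , ] <- Bm[dest - lg, , , drop = FALSE]
      X[ok, (seq_len(nch) - 1L) * nlag + li] <-
        matrix(shifted, nte * ntrials, nch)
    }
    ids <- attr(behavior, "channel_ids")
    if (is.null(ids)) ids <- as.character(seq_len(nch))
    info <- data.frame(kind = "behavior",
                       id = rep(ids, each = nlag),
                       offset = rep(lags, nch))
    list(X = X, info = info)
  }

  part <- switch(kind,
                 auditory = make_aud(),
                 behavioral = make_beh(),
                 full = {
                   a <- make_aud(); b <- make_beh()
                   list(X = cbind(a$X, b$X), info = rbind(a$info, b$info))
                 })
  structure(list(values = part$X, col_info = part$info, kind = kind,
                 trial = rows$trial, bin = rows$bin, trial_meta = trial_meta,
                 lags = lags, pad = pad, n_t_enc = nte, n_sounds = na),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix (%s): %d rows x %d columns\n", x$kind,
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  %d trials x (%d bins + 2 x %d pad rows); lags %s\n",
              nrow(x$trial_meta), x$n_t_enc, x$pad,
              paste(range(x$lags), collapse = "..")))
  invisible(x)
}

# Single-trial sound-plus-noise component of a tensor: D - M - V, restricted
# to the encoding bins, reshaped to [n_t_enc, trial, channel] with trials in
# canonical (video-fastest) order.
single_trial_component <- function(D, marg, enc) {
  d <- dim(D)
  nt <- d[1]; nv <- d[2]; na <- d[3]; nr <- d[4]; nc <- d[5]
  Y <- unclass(D)
  for (v in seq_len(nv)) {
    sub <- marg$M + marg$V[, v, ]
    for (a in seq_len(na)) for (r in seq_len(nr))
      Y[, v, a, r, ] <- Y[, v, a, r, ] - sub
  }
  array(Y[enc, , , , , drop = FALSE], dim = c(length(enc), nv * na * nr, nc))
}

#' Project single-trial activity onto the auditory PC basis
#'
#' Builds the encoding-model target `Y`: the single-trial sound-plus-noise
#' activity (`D - M - V`), projected onto the top `n_components` PCs of the
#' full-dataset sound-related activity, laid out in the same padded row
#' order as [build_design()].
#'
#' @param D neural `trial_tensor`.
#' @param marg its [marginalize()] decomposition (full dataset).
#' @param W_full channel-space PC weights computed on the full dataset (see
#'   [component_pcs()]); only the first `n_components` columns are used.
#' @param n_components dimensionality of the target (4 for sound-related
#'   activity).
#' @param pad NA pad rows per trial edge (must match the design).
#' @return matrix (padded rows x components) with NA pad rows.
#' @export
project_target <- function(D, marg, W_full, n_components = 4,
                           pad = 12) {
  d <- dim(D)
  if (nrow(W_full) != d[5]) stop_arg("W_full does not match the channel count")
  if (n_components > ncol(W_full)) stop_arg("n_components exceeds basis size")
  enc <- encoding_bins(D)
  Ym <- single_trial_component(D, marg, enc)
  ntr <- dim(Ym)[2]
  proj <- matrix(Ym, length(enc) * ntr, d[5]) %*%
    W_full[, seq_len(n_components), drop = FALSE]
  rows <- encoding_rows(length(enc), pad, ntr)
  out <- matrix(NA_real_, length(rows$trial), n_components)
  out[!is.na(rows$bin), ] <- proj
  out
}

#' Principal-component basis of a marginal component
#'
#' PCA channel weights of the sound- or video-related component, computed on
#' whatever data the component came from (train half or full dataset). Signs
#' follow the positive-mean-weight convention.
#'
#' @param marg a [marginalize()] object.
#' @param kind `"sound"` or `"video"`.
#' @param n_components columns to return (default all).
#' @return channels x components weight matrix.
#' @export
component_pcs <- function(marg, kind = c("sound", "video"), n_components = NULL) {
  kind <- match.arg(kind)
  comp <- if (kind == "sound") marg$A else marg$V
  mat <- flatten_component(comp)
  np <- if (is.null(n_components)) ncol(mat) else n_components
  ee <- eigen(crossprod(mat), symmetric = TRUE)
  W <- ee$vectors[, seq_len(np), drop = FALSE]
  flip <- colMeans(W) < 0
  W[, flip] <- -W[, flip]
  W
}

# Plain ridge solve: B = (X'X + lambda I)^-1 X'Y given precomputed moments.
ridge_solve <- function(XtX, XtY, lambda) {
  p <- nrow(XtX)
  A <- XtX + diag(lambda, p)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-8 * mean(diag(XtX)) + 1e-12
    ch <- chol(A + diag(jit, p))
  }
  backsolve(ch, forwardsolve(t(ch), XtY))
}

#' Fit a ridge encoding model
#'
#' Solves `min ||Y - XB||^2 + lambda ||B||^2` on the training-half rows of a
#' design matrix, with the penalty chosen from `lambda_grid` by 3-fold
#' cross-validation over contiguous trial blocks within the training half
#' (ties toward the smaller penalty). Rows containing NA (trial-edge pads
#' and lag spill-over) are excluded from fitting and evaluation. All-zero
#' predictor columns are retained with a warning — the ridge penalty keeps
#' the solve well posed.
#'
#' @param design a [build_design()] object.
#' @param Y target matrix from [project_target()] (same row layout).
#' @param lambda_grid candidate penalties (default `10^(-3..5)`).
#' @param split a [repeat_split()]; training rows come from the train
#'   repeats.
#' @param n_folds inner cross-validation folds.
#' @return object of class `encoding_fit`: `B` (columns x components),
#'   `lambda_selected`, `cv_sse`, `kind`, and the training row mask.
#' @export
fit_ridge <- function(design, Y, lambda_grid = 10^seq(-3, 5),
                      split = repeat_split(max(design$trial_meta$r)),
                      n_folds = 3) {
  if (!length(lambda_grid)) stop_arg("lambda_grid is empty")
  X <- design$values
  if (nrow(X) != nrow(Y)) stop_arg("design and target row counts differ")
  ok <- !is.na(design$bin) & rowSums(is.na(X)) == 0L & rowSums(is.na(Y)) == 0L
  zero_cols <- colSums(abs(X[ok, , drop = FALSE])) == 0
  if (any(zero_cols))
    warning(sum(zero_cols), " all-zero predictor column(s) retained",
            call. = FALSE)
  train_trials <- which(design$trial_meta$r %in% split$train)
  rows_tr <- which(ok & design$trial %in% train_trials)
  if (!length(rows_tr))
    stop_arg("no complete training rows (lag span may exceed the trial window)")

  # contiguous trial blocks for the inner CV
  tr_ids <- unique(design$trial[rows_tr])
  blocks <- split(tr_ids, cut(seq_along(tr_ids), n_folds, labels = FALSE))
  Xtr <- X[rows_tr, , drop = FALSE]
  Ytr <- Y[rows_tr, , drop = FALSE]
  XtX_all <- crossprod(Xtr)
  XtY_all <- crossprod(Xtr, Ytr)
  cv_sse <- rep(0, length(lambda_grid))
  for (b in blocks) {
    in_b <- design$trial[rows_tr] %in% b
    Xv <- Xtr[in_b, , drop = FALSE]
    Yv <- Ytr[in_b, , drop = FALSE]
    XtX_f <- XtX_all - crossprod(Xv)
    XtY_f <- XtY_all - crossprod(Xv, Yv)
    for (li in seq_along(lambda_grid)) {
      Bf <- ridge_solve(XtX_f, XtY_f, lambda_grid[li])
      cv_sse[li] <- cv_sse[li] + sum((Yv - Xv %*% Bf)^2)
    }
  }
  best <- which.min(cv_sse)
  B <- ridge_solve(XtX_all, XtY_all, lambda_grid[best])
  structure(list(B = B, lambda_selected = lambda_grid[best],
                 lambda_grid = lambda_grid, cv_sse = cv_sse,
                 kind = design$kind, n_components = ncol(Y),
                 rows_train = rows_tr, ok = ok),
            class = "encoding_fit")
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("Ridge encoding fit (%s model): %d predictors -> %d components\n",
              x$kind, nrow(x$B), x$n_components))
  cat(sprintf("  lambda = %g (3-fold CV over %d candidates)\n",
              x$lambda_selected, length(x$lambda_grid)))
  invisible(x)
}

#' @export
predict.encoding_fit <- function(object, design, ...) {
  X <- design$values
  out <- matrix(NA_real_, nrow(X), object$n_components)
  ok <- rowSums(is.na(X)) == 0L & !is.na(design$bin)
  out[ok, ] <- X[ok, , drop = FALSE] %*% object$B
  out
}

# Group means of a padded row matrix over (sound, bin) cells for a subset of
# trials; returns a (cells x components) matrix and the cell ids.
sound_bin_means <- function(values, design, trials) {
  use <- design$trial %in% trials & !is.na(design$bin) &
    rowSums(is.na(values)) == 0L
  g <- (design$trial_meta$a[design$trial[use]] - 1L) * design$n_t_enc +
    design$bin[use]
  sums <- rowsum(values[use, , drop = FALSE], g)
  cnt <- as.numeric(table(g))
  list(means = sums / cnt, cells = as.integer(rownames(sums)))
}

#' Trial-averaged prediction quality of an encoding model
#'
#' Averages the target and the model prediction over all test-half trials of
#' each sound, and reports the elementwise Pearson correlation of the two
#' (bins x sounds x components) mean matrices — flattened by default, per
#' component on request. Quantifies how well the model captures the mean
#' sound-evoked time courses.
#'
#' @param fit an [fit_ridge()] object.
#' @param design,Y the design and target the fit was made on.
#' @param split the outer split; evaluation uses the test repeats.
#' @param per_component return one correlation per target component.
#' @return correlation (scalar, or vector if `per_component`). NA when
#'   either matrix has no variance.
#' @export
evaluate_trial_average <- function(fit, design, Y, split, per_component = FALSE) {
  pred <- predict(fit, design)
  test_trials <- which(design$trial_meta$r %in% split$test)
  gy <- sound_bin_means(Y, design, test_trials)
  gp <- sound_bin_means(pred, design, test_trials)
  common <- intersect(gy$cells, gp$cells)
  my <- gy$means[match(common, gy$cells), , drop = FALSE]
  mp <- gp$means[match(common, gp$cells), , drop = FALSE]
  if (per_component)
    vapply(seq_len(ncol(my)), function(j) safe_cor(my[, j], mp[, j]), 0)
  else
    safe_cor(as.numeric(my), as.numeric(mp))
}

#' Trial-to-trial (noise) prediction quality of an encoding model
#'
#' Subtracts from both the test-half target and the test-half prediction the
#' respective mean response to each sound, and correlates the residuals.
#' This isolates the trial-by-trial fluctuations around the sound means: a
#' purely stimulus-driven model predicts identical responses on every repeat
#' of a sound, so its residual prediction is identically zero and the
#' correlation is undefined (returned as NA) — only models with single-trial
#' predictors can score here.
#'
#' @inheritParams evaluate_trial_average
#' @return residual correlation (NA if either residual is constant).
#' @export
evaluate_noise_correlation <- function(fit, design, Y, split,
                                       per_component = FALSE) {
  pred <- predict(fit, design)
  test_trials <- which(design$trial_meta$r %in% split$test)
  use <- design$trial %in% test_trials & !is.na(design$bin) &
    rowSums(is.na(Y)) == 0L & rowSums(is.na(pred)) == 0L
  g <- (design$trial_meta$a[design$trial[use]] - 1L) * design$n_t_enc +
    design$bin[use]
  resid_of <- function(vals) {
    v <- vals[use, , drop = FALSE]
    mu <- rowsum(v, g) / as.numeric(table(g))
    v - mu[match(g, sort(unique(g))), , drop = FALSE]
  }
  ry <- resid_of(Y)
  rp <- resid_of(pred)
  # a stimulus-only model predicts identical responses on every repeat, so
  # its residual is zero up to floating-point noise: report NA, not a
  # meaningless correlation of rounding errors
  if (max(abs(rp)) < 1e-10 * max(abs(ry), 1e-300)) {
    if (per_component) return(rep(NA_real_, ncol(ry)))
    return(NA_real_)
  }
  if (per_component)
    vapply(seq_len(ncol(ry)), function(j) safe_cor(ry[, j], rp[, j]), 0)
  else
    safe_cor(as.numeric(ry), as.numeric(rp))
}

#' Lag profile of a behavioral predictor's weights
#'
#' Extracts, from a behavioral or full encoding fit, the ridge weights of
#' one behavioral channel across all lags, for one target component.
#'
#' @param fit an [fit_ridge()] object.
#' @param design the matching design.
#' @param channel channel id (as in the design's `col_info$id`).
#' @param component target component index.
#' @return named numeric vector (one weight per lag).
#' @export
lag_weights <- function(fit, design, channel, component = 1) {
  sel <- design$col_info$kind == "behavior" & design$col_info$id == channel
  if (!any(sel)) stop_arg("channel not found in the design")
  w <- fit$B[sel, component]
  names(w) <- design$col_info$offset[sel]
  w
}

#' Pixel-space image of motion-PC encoding weights
#'
#' Maps encoding weights on the motion-energy PCs back to pixel space as the
#' weighted sum of the per-PC spatial masks, visualizing which facial
#' regions drive the predicted activity.
#'
#' @param b0_body weights on the motion PCs (e.g. the lag-0 weights
#'   predicting the first auditory PC), length = number of PCs.
#' @param masks PCs x pixels matrix of spatial weights (e.g.
#'   `truth$pixel_masks`).
#' @param mask_dim image dimensions (rows, cols).
#' @return matrix image of per-pixel weights.
#' @export
pixel_weight_map <- function(b0_body, masks, mask_dim = NULL) {
  b0_body <- as.numeric(b0_body)
  if (length(b0_body) != nrow(masks))
    stop_arg("weight count does not match the number of masks")
  img <- as.numeric(b0_body %*% masks)
  if (!is.null(mask_dim)) img <- matrix(img, mask_dim[1], mask_dim[2])
  img
}
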
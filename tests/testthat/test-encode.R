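# Encoding designs, ridge fits and their evaluations, on tensors built in
# code. random_tensor/analysis fixtures carry rel_times from -1 s, so the
# encoding bins are the tail of the window.

test_that("design matrices have the documented structure", {
  D <- random_tensor(40, 2, 3, 4, 3, seed = 501)   # 7 encoding bins
  nte <- sum(attr(D, "rel_times") >= 0)
  expect_equal(nte, 7)
  lags <- -1:2
  da <- build_design("auditory", D, lags = lags)
  expect_equal(ncol(da$values), 3 * nte)
  expect_equal(nrow(da$values), (nte + 2 * length(lags)) * 2 * 3 * 4)
  ok <- !is.na(da$bin)
  # pad rows are all-NA; in-trial rows carry exactly one indicator, in the
  # column block of the trial's sound
  expect_true(all(is.na(da$values[!ok, ])))
  expect_true(all(rowSums(da$values[ok, ]) == 1))
  hit <- max.col(da$values[ok, ])
  expect_equal((hit - 1) %/% nte + 1, da$trial_meta$a[da$trial[ok]])
  expect_equal((hit - 1) %% nte + 1, da$bin[ok])

  B <- random_tensor(40, 2, 3, 4, 2, seed = 502, channel_kind = "behavioral")
  db <- build_design("behavioral", D, behavior = B, lags = lags)
  expect_equal(ncol(db$values), 2 * length(lags))
  dfull <- build_design("full", D, behavior = B, lags = lags)
  expect_equal(ncol(dfull$values), 3 * nte + 2 * length(lags))
  expect_equal(dfull$values[, 1:(3 * nte)], da$values)
  # behavioral entries are NA exactly where the lag leaves the trial window
  col1 <- db$values[db$trial == 1, 1]          # channel 1, lag -1
  expect_true(is.na(col1[length(lags) + nte])) # last in-trial row needs t+1
  expect_error(build_design("behavioral", D, behavior = B,
                            lags = -1:2, pad = 1), "lag span")
  expect_error(build_design("behavioral", D), "behavioral tensor")
})

test_that("behavioral design columns are lagged copies of the marginalized channels", {
  D <- random_tensor(40, 2, 2, 4, 2, seed = 503)
  B <- random_tensor(40, 2, 2, 4, 2, seed = 504, channel_kind = "behavioral")
  bm <- marginalize(B)
  db <- build_design("behavioral", D, behavior = B, behavior_marg = bm,
                     lags = -1:2)
  # oracle: B - M - V at the encoding bins, indexed by hand
  enc <- which(attr(B, "rel_times") >= 0)
  single <- unclass(B)
  for (v in 1:2) for (a in 1:2) for (r in 1:4)
    single[, v, a, r, ] <- single[, v, a, r, ] - bm$M - bm$V[, v, ]
  nte <- length(enc)
  for (trial in c(1, 7)) {
    v <- db$trial_meta$v[trial]; a <- db$trial_meta$a[trial]
    r <- db$trial_meta$r[trial]
    rows <- which(db$trial == trial & !is.na(db$bin))
    for (li in seq_along(db$lags)) {
      lg <- db$lags[li]
      for (j in seq_len(nte)) {
        want <- if (j - lg >= 1 && j - lg <= nte)
          single[enc[j - lg], v, a, r, 1] else NA_real_
        expect_equal(db$values[rows[j], (1 - 1) * 4 + li], want)
      }
    }
  }
})

test_that("shifting a channel in time shifts its recovered lag profile", {
  D <- random_tensor(40, 1, 2, 4, 1, seed = 505)
  B <- random_tensor(40, 1, 2, 4, 1, seed = 506, channel_kind = "behavioral")
  Bs <- unclass(B)
  Bs[2:40, , , , ] <- Bs[1:39, , , , ]   # channel delayed by one bin
  attributes(Bs) <- attributes(B)
  d1 <- build_design("behavioral", D, behavior = B, lags = -2:3)
  d2 <- build_design("behavioral", D, behavior = Bs, lags = -2:3)
  # the delayed channel at lag l carries what the original carried one lag
  # later: column(l) of the shifted design == column(l + 1) of the original
  for (li in 1:5) {
    a <- d2$values[, li]; b <- d1$values[, li + 1]
    ok <- !is.na(a) & !is.na(b)
    expect_gt(sum(ok), 0)
    expect_equal(a[ok], b[ok], tolerance = 1e-10)
  }
})

test_that("the target projection matches an explicit loop", {
  D <- random_tensor(40, 2, 2, 2, 3, seed = 507)
  marg <- marginalize(D)
  W <- component_pcs(marg, "sound")
  Y <- project_target(D, marg, W, n_components = 2, pad = 4)
  enc <- which(attr(D, "rel_times") >= 0)
  rows <- soundmotion:::encoding_rows(length(enc), 4, 8)
  for (trial in c(2, 5)) {
    v <- ((trial - 1) %% 2) + 1
    a <- (((trial - 1) %/% 2) %% 2) + 1
    r <- ((trial - 1) %/% 4) + 1
    rr <- which(rows$trial == trial & !is.na(rows$bin))
    for (j in seq_along(enc)) {
      x <- D[enc[j], v, a, r, ] - marg$M[enc[j], ] - marg$V[enc[j], v, ]
      expect_equal(Y[rr[j], ], as.numeric(x %*% W[, 1:2]), tolerance = 1e-10)
    }
  }
  # D = M + V exactly -> target is identically zero
  D0 <- toy_tensor(40, 2, 2, 2, 3, function(t, v, a, r, c) t * 0.1 + v)
  m0 <- marginalize(D0)
  Y0 <- project_target(D0, m0, W, n_components = 2, pad = 4)
  expect_lt(max(abs(Y0), na.rm = TRUE), 1e-10)
})

test_that("ridge at lambda = 0 is exact least squares; weights shrink with lambda", {
  D <- random_tensor(40, 2, 2, 4, 2, seed = 508)
  da <- build_design("auditory", D, lags = -1:2)
  set.seed(509)
  B0 <- matrix(rnorm(ncol(da$values) * 2), ncol(da$values), 2)
  Y <- da$values %*% B0
  split <- repeat_split(4)
  f0 <- fit_ridge(da, Y, lambda_grid = 0, split = split)
  expect_lt(max(abs(f0$B - B0)), 1e-6)
  expect_equal(f0$lambda_selected, 0)
  # shrinkage monotonicity
  Yn <- Y + matrix(rnorm(length(Y), 0, 0.5), nrow(Y))
  f1 <- fit_ridge(da, Yn, lambda_grid = 0.1, split = split)
  f2 <- fit_ridge(da, Yn, lambda_grid = 10, split = split)
  expect_gte(sum(f1$B^2), sum(f2$B^2))
  expect_error(fit_ridge(da, Yn, lambda_grid = numeric(0), split = split),
               "empty")
  expect_error(fit_ridge(da, Yn[1:10, , drop = FALSE], split = split),
               "row counts")
})

test_that("a planted lagged behavioral kernel is recovered at its lag", {
  set.seed(510)
  B <- random_tensor(60, 1, 2, 4, 1, channel_kind = "behavioral")
  D <- random_tensor(60, 1, 2, 4, 1)
  bm <- marginalize(B)
  db <- build_design("behavioral", D, behavior = B, behavior_marg = bm,
                     lags = -2:5)
  # y(t) = 2 * x(t - 2 bins) + small noise, x the marginalized channel
  X <- db$values
  ok <- rowSums(is.na(X)) == 0
  lag2_col <- which(db$col_info$offset == 2)
  y <- matrix(NA_real_, nrow(X), 1)
  y[ok, 1] <- 2 * X[ok, lag2_col] + rnorm(sum(ok), 0, 0.05)
  fit <- fit_ridge(db, y, lambda_grid = 0.01, split = repeat_split(4))
  w <- lag_weights(fit, db, channel = "1")
  expect_equal(as.integer(names(which.max(abs(w)))), 2L)
  expect_equal(unname(w[which.max(abs(w))]), 2, tolerance = 0.1)
})

test_that("trial-average and noise evaluations behave at their fixed points", {
  D <- random_tensor(40, 2, 2, 4, 3, seed = 511)
  marg <- marginalize(D)
  W <- component_pcs(marg, "sound")
  Y <- project_target(D, marg, W, 2, pad = 4)
  split <- repeat_split(4)
  B <- random_tensor(40, 2, 2, 4, 2, seed = 512, channel_kind = "behavioral")
  db <- build_design("behavioral", D, behavior = B, lags = -1:2)
  # a perfect single-trial predictor: correlation 1 for both metrics
  perfect <- structure(list(B = diag(ncol(db$values))[, 1:2],
                            n_components = 2), class = "encoding_fit")
  X <- db$values
  Yp <- matrix(NA_real_, nrow(X), 2)
  okp <- rowSums(is.na(X)) == 0
  Yp[okp, ] <- X[okp, 1:2]
  expect_equal(evaluate_trial_average(perfect, db, Yp, split), 1)
  expect_equal(evaluate_noise_correlation(perfect, db, Yp, split), 1)
  # an all-zero prediction has no variance: undefined -> NA
  zero_fit <- structure(list(B = matrix(0, ncol(db$values), 2),
                             n_components = 2), class = "encoding_fit")
  expect_true(is.na(evaluate_trial_average(zero_fit, db, Y[, 1:2], split)))
  # a stimulus-only model is constant across repeats: noise correlation NA
  da <- build_design("auditory", D, lags = -1:2)
  fa <- fit_ridge(da, Y, lambda_grid = 1, split = split)
  expect_true(is.na(evaluate_noise_correlation(fa, da, Y, split)))
})

test_that("pixel weight maps are the weighted mask sums", {
  set.seed(513)
  masks <- matrix(rnorm(5 * 12), 5, 12)
  one_hot <- c(0, 0, 1, 0, 0)
  expect_equal(pixel_weight_map(one_hot, masks), masks[3, ])
  expect_equal(pixel_weight_map(rep(0, 5), masks), rep(0, 12))
  b <- rnorm(5)
  oracle <- vapply(1:12, function(p) sum(b * masks[, p]), 0)
  expect_equal(pixel_weight_map(b, masks), oracle, tolerance = 1e-12)
  img <- pixel_weight_map(b, masks, mask_dim = c(3, 4))
  expect_equal(dim(img), c(3, 4))
  expect_error(pixel_weight_map(b[1:3], masks), "match")
})
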
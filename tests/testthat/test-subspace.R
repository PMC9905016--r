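test_that("lagged motion designs are exact shifted copies", {
  set.seed(601)
  x <- matrix(rnorm(50), 50, 1)
  lag3 <- build_lagged_motion(x, 3)
  expect_equal(ncol(lag3$values), 3)
  expect_equal(lag3$lags, -1:1)
  rows <- lag3$rows
  expect_equal(lag3$values[, 1], x[rows + 1, 1])   # lag -1: future sample
  expect_equal(lag3$values[, 2], x[rows, 1])
  expect_equal(lag3$values[, 3], x[rows - 1, 1])   # lag +1: past sample
  # one PC, one lag: the identity design (nothing trimmed)
  lag1 <- build_lagged_motion(x, 1)
  expect_equal(lag1$values[, 1], x[, 1])
  expect_error(build_lagged_motion(x, 4), "odd")
  expect_error(build_lagged_motion(x[1:10, , drop = FALSE], 21), "shorter")
})

test_that("full-rank reduced-rank regression is ordinary least squares", {
  set.seed(602)
  X <- matrix(rnorm(200 * 5), 200, 5)
  B0 <- matrix(rnorm(5 * 4), 5, 4)
  S <- X %*% B0 + matrix(rnorm(200 * 4, 0, 0.1), 200, 4)
  fit <- fit_rrr(X, S, rank = 4)
  Xc <- scale(X, scale = FALSE); Sc <- scale(S, scale = FALSE)
  B_ols <- solve(crossprod(Xc), crossprod(Xc, Sc))
  expect_lt(max(abs(coef(fit) - B_ols)), 1e-6)
  expect_lt(max(abs(crossprod(fit$C) - diag(4))), 1e-8)
})

test_that("a planted low-rank map is recovered as a subspace", {
  set.seed(603)
  X <- matrix(rnorm(2000 * 10), 2000, 10)
  L0 <- matrix(rnorm(10 * 3), 10, 3)
  R0 <- matrix(rnorm(3 * 6), 3, 6)
  S <- X %*% L0 %*% R0 + matrix(rnorm(2000 * 6, 0, 1e-4), 2000, 6)
  fit <- fit_rrr(X, S, rank = 3)
  # principal angle between span(C) and the row space of R0
  Q0 <- qr.Q(qr(t(R0)))
  sv <- svd(crossprod(Q0, fit$C))$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-3)
  # rank bound on the coefficient matrix
  expect_lte(sum(svd(coef(fit))$d > 1e-8), 3)
})

test_that("regressing independent activity explains almost nothing", {
  set.seed(604)
  X <- matrix(rnorm(10000 * 10), 10000, 10)
  S <- matrix(rnorm(10000 * 5), 10000, 5)
  fit <- fit_rrr(X, S, rank = 5)
  fitted <- scale(X, scale = FALSE) %*% coef(fit)
  expect_lt(sum(fitted^2) / sum(scale(S, scale = FALSE)^2), 0.05)
})

test_that("the movement subspace is invariant to design reparameterization", {
  set.seed(605)
  X <- matrix(rnorm(500 * 6), 500, 6)
  S <- X %*% matrix(rnorm(6 * 5), 6, 5) + matrix(rnorm(500 * 5, 0, 0.2), 500, 5)
  Tm <- matrix(rnorm(36), 6, 6)          # invertible reparameterization
  f1 <- fit_rrr(X, S, rank = 2)
  f2 <- fit_rrr(X %*% Tm, S, rank = 2)
  P1 <- f1$C %*% t(f1$C)
  P2 <- f2$C %*% t(f2$C)
  expect_lt(max(abs(P1 - P2)), 1e-6)
})

test_that("subspace overlap hits its analytic endpoints", {
  set.seed(606)
  u <- rnorm(60); w <- qr.Q(qr(matrix(rnorm(8 * 2), 8, 2)))
  sig <- outer(u, w[, 1]) + outer(rev(u), w[, 2])   # exact rank 2
  A <- array(sig, c(12, 5, 8))
  hm_tr <- A; hm_te <- A
  cv <- cvpca_spectrum(hm_tr, hm_te)
  # C = the top-2 auditory PCs: overlap exactly 1
  ov <- subspace_overlap(hm_tr, hm_te, cv$W[, 1:2], k = 2,
                         auditory_vhat = cv, n_random = 100, seed = 607)
  expect_lt(abs(ov$overlap_ratio - 1), 1e-6)
  # C orthogonal to all signal: overlap exactly 0
  Cperp <- qr.Q(qr(cbind(w, matrix(rnorm(8 * 6), 8, 6))))[, 3:4]
  ov0 <- subspace_overlap(hm_tr, hm_te, Cperp, k = 2,
                          auditory_vhat = cv, n_random = 100, seed = 608)
  expect_lt(abs(ov0$overlap_ratio), 1e-10)
  expect_error(subspace_overlap(hm_tr, hm_te, cv$W[, 1:2] * 2, k = 2,
                                auditory_vhat = cv), "orthonormal")
  expect_error(subspace_overlap(hm_tr, hm_te, cv$W[, 1:2], k = 5,
                                auditory_vhat = cv), "dimensions")
})

test_that("cross-correlogram lags recover planted shifts and reject junk", {
  set.seed(609)
  x <- as.numeric(arima.sim(list(ar = 0.8), 3000))
  y <- c(rep(0, 3), x[1:(3000 - 3)])     # y lags x by 3 samples
  xc <- xcorr_lag(x, y, rate = 40, max_lag = 0.5)
  expect_equal(xc$lag, 3 / 40, tolerance = 1e-9)
  expect_gt(xc$peak, 0.9)
  # independent white noise: no structure
  xc0 <- xcorr_lag(rnorm(4000), rnorm(4000), rate = 40, max_lag = 0.5)
  expect_lt(abs(xc0$peak), 3 / sqrt(4000) + 0.02)
  expect_error(xcorr_lag(rep(1, 100), rnorm(100), 40), "constant")
  expect_error(xcorr_lag(rnorm(10), rnorm(10), 40, max_lag = 2), "short")
})

test_that("weight-peak delays read off the lag grid", {
  w <- c(0.1, 0.2, 1.5, 0.3, 0.1)
  expect_equal(weight_peak_delay(w, -2:2, rate = 40), 0)
  expect_equal(weight_peak_delay(c(0, 0.1, 0.2, 0.9, 0.3), -2:2, 40), 1 / 40)
  # symmetric acausal profile peaks at zero lag
  expect_equal(weight_peak_delay(c(0.2, 0.5, 1, 0.5, 0.2), -2:2, 40), 0)
  expect_warning(d <- weight_peak_delay(rep(0, 5), -2:2, 40), "flat")
  expect_true(is.na(d))
})
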
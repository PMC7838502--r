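test_that("omega matrix reproduces the printed r = 1 kernel exactly", {
  om <- omega_matrix(1)
  expect_identical(unclass(om)[1:3, 1:3],
                   matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16)
  expect_identical(unclass(omega_matrix(0))[1, 1], 1)
  # r = 2: entries 2^(4 - d) with city-block d, then normalized
  om2 <- omega_matrix(2, normalized = FALSE)
  d <- outer(abs(-2:2), abs(-2:2), `+`)
  expect_identical(unclass(om2)[1:5, 1:5], 2^(4 - d))
  expect_equal(sum(omega_matrix(2)), 1)
  expect_error(omega_matrix(-1), "non-negative")
})

test_that("ZCA whitening decorrelates and respects fixed points", {
  # orthonormal rows: S S^T = I, so K -> I as eta -> 0
  q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  S <- array(q, c(8, 8, 1))
  expect_lt(max(abs(zca_whiten(S, 1e-10) - S)), 1e-4)
  # whitened covariance is (near) identity (well-conditioned instance:
  # deviation is eta / (lambda_min + eta), so lambda_min must dominate eta)
  set.seed(3)
  S2 <- array(rnorm(64, sd = 3), c(8, 8, 1))
  Sh <- zca_whiten(S2, 1e-5)
  expect_lt(max(abs(tcrossprod(Sh[, , 1]) - diag(8))), 1e-3)
  # eigendecomposition oracle: K Co K^T ~ I
  Co <- tcrossprod(S2[, , 1])
  ei <- eigen(Co, symmetric = TRUE)
  K <- ei$vectors %*% ((ei$values + 1e-5)^-0.5 * t(ei$vectors))
  expect_lt(max(abs(K %*% S2[, , 1] - Sh[, , 1])), 1e-8)
  # all-zero channel stays zero without error
  expect_equal(zca_whiten(array(0, c(6, 6, 2)), 1e-5),
               array(0, c(6, 6, 2)))
  expect_error(zca_whiten(array(NA_real_, c(4, 4, 1))), "non-finite")
  expect_error(zca_whiten(array(1, c(4, 4, 1)), eta = 0), "positive")
})

test_that("l1 window average matches closed forms and the brute-force oracle", {
  # constant stack of value a over C channels -> C * |a|
  S <- array(-0.3, c(10, 10, 4))
  expect_equal(l1_window_average(S, 2), matrix(4 * 0.3, 10, 10))
  # single-channel impulse, k = 2 -> 1/25 inside the 5x5 neighborhood
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  W <- l1_window_average(array(imp, c(11, 11, 1)), 2)
  expect_equal(W[6, 6], 1 / 25)
  expect_equal(W[4, 4], 1 / 25)
  expect_equal(W[3, 6], 0)
  set.seed(8)
  S3 <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  expect_lt(max(abs(l1_window_average(S3, 2) - bf_l1_window_average(S3, 2))),
            1e-12)
  # bounded by C * max |S|
  expect_lte(max(l1_window_average(S3, 2)), 3 * max(abs(S3)))
  expect_gte(min(l1_window_average(S3, 2)), 0)
})

test_that("WLE, EML and WSEML match closed forms and the brute-force oracle", {
  om <- omega_matrix(1)
  cW <- matrix(0.7, 12, 12)
  expect_equal(wle(cW, om), matrix(0.49, 12, 12))
  expect_equal(wseml(cW, om), matrix(0, 12, 12))
  # impulse WLE at center = central omega weight
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  expect_equal(wle(imp, om)[5, 5], 4 / 16)
  expect_equal(wle(matrix(0, 5, 5), om), matrix(0, 5, 5))
  # linear ramp kills second differences in the interior
  ramp <- matrix(seq_len(12), 12, 12)
  expect_equal(eml(ramp)[2:11, 2:11], matrix(0, 10, 10))
  expect_equal(wseml(ramp, om)[3:10, 3:10], matrix(0, 8, 8))
  # checkerboard: EML = 4 interior, WSEML = 4 interior
  cb <- checkerboard(10)
  expect_equal(eml(cb)[2:9, 2:9], matrix(4, 8, 8))
  expect_equal(wseml(cb, om)[3:8, 3:8], matrix(4, 6, 6))
  # seeded random maps agree with the loop oracle to 1e-12
  set.seed(21)
  W <- matrix(runif(256), 16, 16)
  expect_lt(max(abs(wle(W, om) - bf_wle(W, om))), 1e-12)
  expect_lt(max(abs(eml(W) - bf_eml(W))), 1e-12)
  expect_lt(max(abs(wseml(W, om) - bf_wseml(W, om))), 1e-12)
  expect_error(eml(matrix(1, 2, 2)), "at least")
})

test_that("activity maps transpose with the image (omega is symmetric)", {
  set.seed(5)
  W <- matrix(runif(15 * 11), 15, 11)
  om <- omega_matrix(1)
  expect_equal(wle(t(W), om), t(wle(W, om)))
  expect_equal(wseml(t(W), om), t(wseml(W, om)))
})

test_that("weight-map fusion follows the selection rule", {
  om <- omega_matrix(1)
  set.seed(31)
  W1 <- matrix(runif(100), 10, 10)
  W2 <- matrix(runif(100), 10, 10)
  fw <- fuse_weight_maps(W1, W2, om)
  # pointwise membership
  expect_true(all(fw$values == W1 | fw$values == W2))
  # agreement with the per-pixel loop oracle on seeded pairs
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(runif(64), 8, 8); B <- matrix(runif(64), 8, 8)
    got <- fuse_weight_maps(A, B, om)
    want <- bf_fuse_weight_maps(A, B, om)
    expect_identical(got$values, want$values)
    expect_identical(got$selection_mask, want$mask)
  }
  # W1 strictly dominant -> all selected from W1
  big <- matrix(rep(c(1, 5), 50), 10, 10)
  small <- matrix(0.01, 10, 10)
  fwd <- fuse_weight_maps(big, small, om)
  expect_identical(fwd$selection_mask, matrix(1, 10, 10))
  expect_identical(fwd$values, big)
  # ties go to the first source
  fwt <- fuse_weight_maps(W1, W1, om)
  expect_identical(fwt$selection_mask, matrix(1, 10, 10))
  expect_identical(fwt$values, W1)
  expect_error(fuse_weight_maps(W1, matrix(0, 9, 9)), "shape")
})

test_that("swapping inputs inverts the selection mask away from ties", {
  set.seed(77)
  W1 <- matrix(runif(144), 12, 12)
  W2 <- matrix(runif(144), 12, 12)
  om <- omega_matrix(1)
  a1 <- wle(W1, om) * wseml(W1, om)
  a2 <- wle(W2, om) * wseml(W2, om)
  f12 <- fuse_weight_maps(W1, W2, om)$selection_mask
  f21 <- fuse_weight_maps(W2, W1, om)$selection_mask
  ties <- a1 == a2
  expect_true(all((f12 + f21 == 1)[!ties]))
})
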
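test_that("entropy hits its closed forms", {
  expect_equal(image_entropy(matrix(0.5, 8, 8)), 0)
  two <- matrix(rep(c(0, 1), 32), 8, 8)
  expect_equal(image_entropy(two), 1)
  # iid uniform over 256 levels approaches 8 bits
  set.seed(1)
  u <- matrix((sample.int(256, 512 * 512, replace = TRUE) - 1) / 255, 512)
  expect_lt(abs(image_entropy(u) - 8), 0.01)
  expect_lte(image_entropy(u), 8)
})

test_that("Q_MI reaches 2 on identical triples and ~0 on independent noise", {
  p <- make_gray_pair(phantom_spec(size = 32, seed = 2))
  expect_equal(metric_qmi(p$a, p$a, p$a), 2)
  set.seed(3)
  n <- 512  # large sample keeps the joint-histogram bias small
  a <- matrix(runif(n * n), n); b <- matrix(runif(n * n), n)
  noise <- matrix(runif(n * n), n)
  q0 <- metric_qmi(a, b, noise)
  expect_lt(q0, 0.1)  # ~0 up to bin-count bias
  # tiny 2x2 triple matches the counting oracle exactly
  i1 <- matrix(c(0, 1, 0.5, 0.25), 2, 2)
  i2 <- matrix(c(1, 0, 0.5, 0.75), 2, 2)
  f <- matrix(c(0.5, 0.5, 0, 1), 2, 2)
  expect_equal(metric_qmi(i1, i2, f), bf_qmi(i1, i2, f))
  # degenerate: constant everything warns and returns 0
  cst <- matrix(0.5, 4, 4)
  expect_warning(expect_warning(q <- metric_qmi(cst, cst, cst),
                                "zero-entropy"), "zero-entropy")
  expect_equal(q, 0)
})

test_that("Q_MI stays within [0, 2] and is permutation invariant", {
  set.seed(4)
  for (s in 1:20) {
    a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
    f <- matrix(runif(64), 8, 8)
    q <- metric_qmi(a, b, f)
    expect_gte(q, 0); expect_lte(q, 2 + 1e-9)
  }
  a <- matrix(runif(100), 10, 10); b <- matrix(runif(100), 10, 10)
  f <- matrix(runif(100), 10, 10)
  perm <- sample(100)
  expect_equal(metric_qmi(a, b, f),
               metric_qmi(matrix(a[perm], 10), matrix(b[perm], 10),
                          matrix(f[perm], 10)))
  expect_equal(metric_scd(a, b, f),
               metric_scd(matrix(a[perm], 10), matrix(b[perm], 10),
                          matrix(f[perm], 10)))
  expect_equal(image_entropy(f), image_entropy(matrix(f[perm], 10)))
})

test_that("Q^AB/F stays in [0, 1] and rewards perfect edge preservation", {
  set.seed(5)
  for (s in 1:100) {
    a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
    f <- matrix(runif(64), 8, 8)
    q <- metric_qabf(a, b, f)
    expect_gte(q, 0); expect_lte(q, 1)
  }
  # F = A = B (non-flat): the logistic ceiling, identical for any such triple
  ceiling_q <- (0.9994 / (1 + exp(-15 * (1 - 0.5)))) *
    (0.9879 / (1 + exp(-22 * (1 - 0.8))))
  p <- make_gray_pair(phantom_spec(size = 32, seed = 6))
  expect_equal(metric_qabf(p$a, p$a, p$a), ceiling_q, tolerance = 1e-10)
  expect_equal(metric_qabf(p$b, p$b, p$b), ceiling_q, tolerance = 1e-10)
  # rotating the fused image degrades orientation preservation
  rot <- t(p$a)[, rev(seq_len(32))]  # 90-degree rotation (square input)
  expect_lt(metric_qabf(p$a, p$a, matrix(rot, 32, 32)),
            metric_qabf(p$a, p$a, p$a))
  expect_warning(q0 <- metric_qabf(matrix(0.3, 8, 8), matrix(0.3, 8, 8),
                                   matrix(0.3, 8, 8)), "flat")
  expect_equal(q0, 0)
})

test_that("SCD matches its closed form and the Pearson oracle", {
  set.seed(7)
  a <- matrix(runif(256), 16, 16); b <- matrix(runif(256), 16, 16)
  expect_equal(metric_scd(a, b, a + b), 2)
  f <- matrix(runif(256), 16, 16)
  expect_equal(metric_scd(a, b, f), metric_scd(b, a, f))
  expect_lt(abs(metric_scd(a, b, f) - bf_scd(a, b, f)), 1e-12)
  expect_warning(expect_warning(
    s0 <- metric_scd(matrix(1, 4, 4) * 0.2, b[1:4, 1:4],
                     matrix(0.2, 4, 4)), "zero-variance"), "zero-variance")
})

test_that("VIFF is 1 for perfect fidelity, near 0 for noise, nonnegative", {
  p <- make_gray_pair(phantom_spec(size = 64, seed = 8))
  expect_equal(metric_viff(p$a, p$a, p$a), 1, tolerance = 1e-6)
  set.seed(9)
  noise <- matrix(runif(64 * 64), 64, 64)
  expect_lt(metric_viff(p$a, p$b, noise), 0.1)
  for (s in 1:10) {
    set.seed(100 + s)
    a <- matrix(runif(32 * 32), 32); b <- matrix(runif(32 * 32), 32)
    f <- matrix(runif(32 * 32), 32)
    expect_gte(metric_viff(a, b, f), 0)
  }
  expect_error(metric_viff(p$a[1:16, 1:16], p$b[1:16, 1:16],
                           p$a[1:16, 1:16]), "32x32")
})

test_that("the combined report carries all five metrics", {
  p <- make_gray_pair(phantom_spec(size = 64, seed = 10))
  rep <- fusion_metrics(p$a, p$b, (p$a + p$b) / 2)
  expect_s3_class(rep, "metric_report")
  expect_true(all(is.finite(unlist(rep[c("en", "q_mi", "q_abf", "scd",
                                         "viff")]))))
  expect_gte(rep$q_abf, 0); expect_lte(rep$q_abf, 1)
  expect_gte(rep$en, 0)
})
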
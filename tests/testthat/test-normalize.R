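test_that("quantile normalization matches the sorted-mean oracle", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(out[, 2]), c(1.5, 3, 4.5))
  # order-scrambled columns hit the same reference values by rank
  m2 <- cbind(a = c(3, 1, 2), b = c(2, 6, 4))
  out2 <- quantile_normalize(m2)
  expect_equal(unname(out2[, 1]), c(4.5, 1.5, 3))
  expect_equal(unname(out2[, 2]), c(1.5, 4.5, 3))
})

test_that("quantile normalization agrees with the independent limma oracle on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(100)
  m <- matrix(rnorm(600), 100, 6)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("quantile normalization properties: equal sorted columns, ranks, idempotence", {
  set.seed(7)
  m <- matrix(rlnorm(300, 5, 1), 100, 3)  # continuous, tie-free
  out <- quantile_normalize(m)
  for (j in 2:3) expect_equal(sort(out[, 1]), sort(out[, j]))
  for (j in 1:3) {
    expect_equal(rank(out[, j]), rank(m[, j]))
  }
  expect_equal(quantile_normalize(out), out, tolerance = 1e-12)
  # identical columns are unchanged
  mm <- cbind(m[, 1], m[, 1])
  expect_equal(quantile_normalize(mm), mm)
})

test_that("quantile ties share the mean of the reference slots they span", {
  m <- cbind(a = c(1, 1, 2), b = c(10, 20, 30))
  # sorted-mean reference: (1+10)/2, (1+20)/2, (2+30)/2 = 5.5, 10.5, 16
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(8, 8, 16))    # tie spans slots 1-2
  expect_equal(unname(out[, "b"]), c(5.5, 10.5, 16))
})

test_that("rsn maps identical columns to identity and removes shifts", {
  set.seed(12)
  base <- sort(rnorm(400, 8, 2))
  m <- cbind(a = base, b = base)
  expect_lt(max(abs(rsn_normalize(m) - m)), 1e-8)
  m2 <- cbind(a = base, b = base + 0.7)
  out <- rsn_normalize(m2)
  # the reference column is untouched; the shifted one lands on it
  expect_equal(out[, "a"], m2[, "a"], ignore_attr = TRUE)
  expect_lt(median(abs(out[, "b"] - base)), 0.02)
  # ranks preserved exactly
  set.seed(13)
  m3 <- matrix(rnorm(900, 8, 2), 300, 3)
  out3 <- rsn_normalize(m3)
  for (j in 1:3) expect_equal(rank(out3[, j]), rank(m3[, j]))
  expect_error(rsn_normalize(matrix(1:5, 5, 1)),
               class = "beadnorm_validation_error")
})

test_that("loess normalization removes intensity-independent offsets", {
  set.seed(14)
  base <- rnorm(500, 8, 2)
  m <- cbind(a = base, b = base, c = base)
  out <- loess_normalize(m)
  expect_equal(out, m, tolerance = 1e-6)
  # a constant offset against the row-mean reference is removed: all
  # columns converge onto the common pseudo-reference
  m2 <- cbind(a = base, b = base, c = base, d = base + 1)
  out2 <- loess_normalize(m2)
  expect_lt(median(abs(out2[, "d"] - out2[, "a"])), 0.05)
  # the global mean is approximately preserved
  set.seed(15)
  m3 <- matrix(rnorm(2000, 8, 2), 500, 4) + rep(c(0, .3, -.2, .1), each = 500)
  expect_lt(abs(mean(loess_normalize(m3)) - mean(m3)), 0.05)
})

test_that("vsn calibrates identical columns identically and handles negatives", {
  set.seed(16)
  base <- rlnorm(300, 5, 1.2) - 20
  m <- cbind(a = base, b = base, c = base)
  out <- vsn_normalize(m)
  pars <- attr(out, "vsn_params")
  expect_equal(unname(pars$offset), rep(unname(pars$offset[1]), 3))
  expect_equal(unname(pars$scale), rep(unname(pars$scale[1]), 3))
  expect_equal(out[, 1], out[, 2], ignore_attr = TRUE)
  expect_true(all(is.finite(out)))
  expect_true(any(m < 0))
})

test_that("vsn approaches log2 plus a constant at high intensities", {
  x <- exp(seq(log(50), log(5e4), length.out = 400))
  m <- cbind(a = x, b = 1.15 * x)
  out <- vsn_normalize(m)
  top <- x >= quantile(x, 0.9)
  d <- out[top, 1] - log2(x[top])
  expect_lt(sd(d), 0.01)
})

test_that("average normalization equalizes column means", {
  m <- cbind(a = c(5, 15), b = c(10, 30))
  out <- average_normalize(m)
  # grand mean 15: columns scaled by 1.5 and 0.75
  expect_equal(unname(out[, 1]), c(7.5, 22.5))
  expect_equal(unname(out[, 2]), c(7.5, 22.5))
  expect_equal(unname(colMeans(out)), rep(15, 2))
  m2 <- cbind(a = c(1, 3), b = c(3, 1))
  expect_equal(average_normalize(m2), m2)
  expect_error(average_normalize(cbind(c(-5, 1), c(1, 2))),
               class = "beadnorm_validation_error")
})

test_that("rank-invariant normalization recovers exact scalings", {
  set.seed(18)
  base <- sort(rlnorm(500, 5, 1))
  m <- cbind(a = base, b = base)
  out <- rank_invariant_normalize(m)
  expect_equal(out, m, tolerance = 1e-10)
  m2 <- cbind(a = base, b = 2 * base)
  out2 <- rank_invariant_normalize(m2)
  # reference is the column nearest the grand mean; mapped column should
  # land near it over the mid-intensity bulk
  mid <- base > quantile(base, 0.1) & base < quantile(base, 0.9)
  ref_col <- out2[mid, which.min(abs(colMeans(m2) - mean(colMeans(m2))))]
  other <- out2[mid, -which.min(abs(colMeans(m2) - mean(colMeans(m2))))]
  expect_lt(median(abs(other - ref_col) / ref_col), 0.05)
  # monotone: output ranks preserved
  set.seed(19)
  m3 <- matrix(rlnorm(1500, 5, 1), 500, 3)
  out3 <- rank_invariant_normalize(m3)
  for (j in 1:3) {
    expect_gt(cor(rank(out3[, j]), rank(m3[, j])), 0.9999)
  }
  # unrelated columns have wildly different ranks: with a tight tolerance
  # the invariant set collapses and the method refuses to fit
  set.seed(21)
  m4 <- cbind(rlnorm(500, 5, 1), rlnorm(500, 5, 1))
  expect_error(rank_invariant_normalize(m4, rank_tol = 0.002),
               "rank_tol", class = "beadnorm_validation_error")
})

test_that("cubic-spline normalization matches quantiles across scaled columns", {
  set.seed(20)
  base <- rlnorm(800, 5, 1)
  m <- cbind(a = base, b = base)
  expect_equal(cubic_spline_normalize(m), m, tolerance = 1e-8)
  m2 <- cbind(a = base, b = 1.8 * base)
  out <- cubic_spline_normalize(m2)
  qa <- quantile(out[, 1], probs = seq(0.05, 0.95, 0.05))
  qb <- quantile(out[, 2], probs = seq(0.05, 0.95, 0.05))
  expect_lt(max(abs(qa - qb) / qa), 0.02)
  for (j in 1:2) expect_equal(rank(out[, j]), rank(m2[, j]))
  expect_error(cubic_spline_normalize(m2, n_anchors = 10000),
               class = "beadnorm_validation_error")
})
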
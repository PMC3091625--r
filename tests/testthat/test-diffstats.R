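test_that("the artificial benchmark mean square equals 4/3", {
  res <- group_msq(list(rep(6, 4), rep(6, 4), rep(7, 4)))
  expect_equal(unname(res["msq_between"]), 4 / 3)
  expect_equal(unname(res["msq_within"]), 0)
  expect_equal(round(unname(res["msq_between"]), 2), 1.33)
})

test_that("group_msq matches the brute-force double loop on random instances", {
  set.seed(41)
  for (i in 1:300) {
    vals <- lapply(sample(2:5, sample(2:4, 1), replace = TRUE),
                   function(n) rnorm(n, sd = runif(1, 0.5, 3)))
    if (sum(lengths(vals)) == length(vals)) next
    expect_equal(group_msq(vals), brute_msq(vals), tolerance = 1e-12)
  }
  # degenerate cases
  expect_equal(unname(group_msq(list(c(1, 1), c(1, 1)))), c(0, 0))
  expect_error(group_msq(list(1, 2)), class = "beadnorm_validation_error")
  expect_error(group_msq(list(c(1, 2))), class = "beadnorm_validation_error")
})

test_that("f_test reproduces the brute-force decomposition and its df", {
  set.seed(42)
  m <- matrix(rnorm(12 * 200, 8), 200, 12,
              dimnames = list(sprintf("p%03d", 1:200), tiny_design()$sample_id))
  an <- f_test(m, tiny_design())
  expect_equal(unique(an$df1), 2)
  expect_equal(unique(an$df2), 9)
  design <- tiny_design()
  for (i in sample(200, 25)) {
    vals <- lapply(split(design$sample_id, design$group), function(s) m[i, s])
    oracle <- brute_msq(vals)
    expect_equal(an$msq_between[i], unname(oracle["msq_between"]),
                 tolerance = 1e-12)
    expect_equal(an$msq_within[i], unname(oracle["msq_within"]),
                 tolerance = 1e-12)
    expect_equal(an$f_stat[i],
                 unname(oracle["msq_between"] / oracle["msq_within"]),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance probes follow the stated F conventions", {
  design <- tiny_design()
  m <- rbind(
    flat = rep(5, 12),                          # both mean squares zero
    step = rep(c(5, 5, 6), each = 4))           # between > 0, within = 0
  colnames(m) <- design$sample_id
  an <- f_test(m, design)
  expect_equal(an$p[an$probe_id == "flat"], 1)
  expect_true(is.na(an$f_stat[an$probe_id == "flat"]))
  expect_equal(an$p[an$probe_id == "step"], 0)
  expect_equal(an$f_stat[an$probe_id == "step"], Inf)
})

test_that("null F-test p-values are approximately uniform", {
  set.seed(43)
  design <- tiny_design()
  m <- matrix(rnorm(5000 * 12), 5000, 12,
              dimnames = list(NULL, design$sample_id))
  an <- f_test(m, design)
  ks <- suppressWarnings(stats::ks.test(an$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(an$p < 0.05) - 0.05), 0.01)
})

test_that("bh_adjust matches the hand oracle and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "beadnorm_validation_error")
  set.seed(44)
  for (i in 1:300) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  # adjusted values are a non-decreasing function of the order statistics
  p <- runif(50)
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= 0))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("moderated t reduces to the ordinary t when d0 = 0", {
  set.seed(45)
  design <- tiny_design()
  m <- matrix(rnorm(12 * 100, 8), 100, 12,
              dimnames = list(sprintf("p%03d", 1:100), design$sample_id))
  mt <- moderated_t(m, design, comparisons = list(c("g2", "g1")),
                    d0_override = 0)
  # ordinary t from the same pooled-variance fit
  an <- f_test(m, design)
  g1 <- design$sample_id[design$group == "g1"]
  g2 <- design$sample_id[design$group == "g2"]
  ratio <- rowMeans(m[, g2]) - rowMeans(m[, g1])
  t_ord <- ratio / sqrt(an$msq_within * (1 / 4 + 1 / 4))
  expect_equal(mt$moderated_t, unname(t_ord), tolerance = 1e-12)
  expect_equal(mt$log2_ratio, unname(ratio))
})

test_that("d0 = Inf gives full shrinkage toward the prior variance", {
  set.seed(46)
  design <- tiny_design()
  m <- matrix(rnorm(12 * 100, 8), 100, 12,
              dimnames = list(NULL, design$sample_id))
  mt <- moderated_t(m, design, comparisons = list(c("g2", "g1")),
                    d0_override = Inf)
  s0 <- sqrt(attr(mt, "s0_sq"))
  expect_equal(mt$moderated_t,
               mt$log2_ratio / (s0 * sqrt(1 / 4 + 1 / 4)), tolerance = 1e-12)
})

test_that("moderated t agrees with the independent limma implementation", {
  skip_if_not_installed("limma")
  set.seed(47)
  design <- tiny_design()
  m <- matrix(rnorm(12 * 400, 8, 1), 400, 12,
              dimnames = list(sprintf("p%03d", 1:400), design$sample_id))
  m[1:40, design$group == "g2"] <- m[1:40, design$group == "g2"] + 1
  mt <- moderated_t(m, design, comparisons = list(c("g2", "g1")))
  X <- stats::model.matrix(~ 0 + factor(design$group,
                                        levels = c("g1", "g2", "g3")))
  colnames(X) <- c("g1", "g2", "g3")
  fit <- limma::lmFit(m, X)
  fit <- limma::contrasts.fit(fit,
                              limma::makeContrasts(g2 - g1, levels = X))
  fit <- limma::eBayes(fit)
  expect_equal(mt$log2_ratio, unname(fit$coefficients[, 1]),
               tolerance = 1e-10)
  expect_gt(cor(mt$moderated_t, fit$t[, 1]), 0.9999)
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 0.2)
  expect_equal(attr(mt, "s0_sq"), fit$s2.prior, tolerance = 0.05)
})

test_that("moderated-t type-I error is controlled on null data", {
  set.seed(48)
  design <- tiny_design()
  m <- matrix(rnorm(12 * 4000, 8), 4000, 12,
              dimnames = list(NULL, design$sample_id))
  mt <- moderated_t(m, design, comparisons = list(c("g3", "g1")))
  rate <- mean(mt$p < 0.05)
  band <- 2.58 * sqrt(0.05 * 0.95 / 4000)  # 99% binomial band
  expect_lt(abs(rate - 0.05), band + 0.005)
})

test_that("residual_sd is sqrt(msq_within), shift-invariant, zero for replicates", {
  set.seed(49)
  design <- tiny_design()
  m <- matrix(rnorm(12 * 80, 8), 80, 12,
              dimnames = list(NULL, design$sample_id))
  rs <- residual_sd(m, design)
  an <- f_test(m, design)
  expect_equal(rs$residual_sd, sqrt(an$msq_within), tolerance = 1e-14)
  rs_shift <- residual_sd(m + 5, design)
  expect_equal(rs_shift$residual_sd, rs$residual_sd, tolerance = 1e-10)
  expect_equal(rs_shift$mean_expr, rs$mean_expr + 5)
  m[1, ] <- rep(c(3, 4, 5), each = 4)
  expect_equal(residual_sd(m, design)$residual_sd[1], 0)
})
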
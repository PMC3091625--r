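make_anova <- function(p_adj, msq_between = NULL, msq_within = NULL, p = NULL) {
  n <- length(p_adj)
  if (is.null(msq_between)) msq_between <- runif(n, 0, 5)
  if (is.null(msq_within)) msq_within <- runif(n, 0, 1)
  if (is.null(p)) p <- p_adj
  tibble::tibble(
    probe_id = sprintf("p%04d", seq_len(n)),
    msq_between = msq_between, msq_within = msq_within,
    f_stat = 1, df1 = 2, df2 = 9, p = p, p_adj = p_adj)
}

test_that("fstat_cdf is the counting ECDF with the highlighted cutoffs", {
  set.seed(51)
  an <- make_anova(runif(500))
  cdf <- fstat_cdf(an)
  expect_true(all(c(0.02, 0.05) %in% cdf$cutoff))
  for (ct in c(0.02, 0.05, 1)) {
    expect_equal(cdf$fraction[cdf$cutoff == ct], mean(an$p_adj <= ct))
  }
  cdf1 <- fstat_cdf(make_anova(rep(1, 10)))
  expect_true(all(cdf1$fraction[cdf1$cutoff < 1] == 0))
  expect_equal(cdf1$fraction[cdf1$cutoff == 1], 1)
  expect_error(fstat_cdf(make_anova(numeric(0))),
               class = "beadnorm_validation_error")
})

test_that("pvalue_vs_msq quantifies scatter around the trend", {
  set.seed(52)
  msq <- runif(400, 0, 4)
  # perfectly monotone relation: no residual scatter
  p <- 10 ^ (-msq)
  s <- pvalue_vs_msq(make_anova(p, msq_between = msq, p = p))
  expect_lt(s$dispersion, 0.05)
  expect_equal(s$flagged_fraction, 0)
  # noisy relation has larger dispersion, matching the residual oracle
  p2 <- 10 ^ (-(msq + rnorm(400, 0, 0.8)))
  s2 <- pvalue_vs_msq(make_anova(p2, msq_between = msq, p = p2))
  expect_gt(s2$dispersion, s$dispersion)
  expect_equal(s2$dispersion,
               median(abs(s2$points$neglog_p - s2$points$trend)))
  # the cap restricts the probe set
  s3 <- pvalue_vs_msq(make_anova(p, msq_between = msq, p = p), msq_cap = Inf)
  expect_equal(nrow(s3$points), 400)
})

test_that("msq_summaries reports the 4/3 benchmark and detects bimodality", {
  set.seed(53)
  an <- make_anova(runif(600), msq_within = abs(rnorm(600, 0.2, 0.05)))
  s <- msq_summaries(an)
  expect_equal(s$benchmark_msq, 4 / 3)
  expect_equal(s$n_within_above_benchmark, sum(an$msq_within > 4 / 3))
  expect_equal(s$mode_count_within, 1)
  an2 <- make_anova(runif(600),
                    msq_within = c(abs(rnorm(300, 0.2, 0.03)),
                                   abs(rnorm(300, 2, 0.2))))
  expect_equal(msq_summaries(an2)$mode_count_within, 2)
})

test_that("volcano_summary sees symmetry and flat trends", {
  set.seed(54)
  ratio <- c(-rev(seq(0.05, 3, 0.05)), seq(0.05, 3, 0.05))
  p <- 10 ^ (-abs(ratio))
  modt <- tibble::tibble(probe_id = sprintf("p%03d", seq_along(ratio)),
                         comparison = "b_vs_a", log2_ratio = ratio,
                         moderated_t = 1, p = p, p_adj = p)
  vs <- volcano_summary(modt)
  expect_lt(vs$asymmetry, 0.05)
  expect_lt(vs$dispersion, 0.05)
  # all-equal p-values: flat trend, zero dispersion
  modt$p <- rep(0.5, nrow(modt))
  vs2 <- volcano_summary(modt)
  expect_equal(vs2$dispersion, 0)
  expect_error(volcano_summary(dplyr::mutate(modt, log2_ratio = 1)),
               class = "beadnorm_validation_error")
})

test_that("residual_sd_trend flags heteroscedasticity via the flatness ratio", {
  set.seed(55)
  n <- 500
  homo <- tibble::tibble(probe_id = as.character(1:n),
                         residual_sd = abs(rnorm(n, 1, 0.01)),
                         mean_expr = runif(n, 4, 12),
                         min_expr = runif(n, 3, 11))
  tr <- residual_sd_trend(homo)
  expect_lt(tr$flatness[["mean"]], 1.1)
  hetero <- dplyr::mutate(homo, residual_sd = 0.1 + (mean_expr - 4) / 2)
  tr2 <- residual_sd_trend(hetero)
  expect_gt(tr2$flatness[["mean"]], 5)
  # binned medians match a direct binning oracle
  bins <- cut(rank(hetero$mean_expr, ties.method = "first"), 10,
              labels = FALSE)
  oracle <- as.numeric(tapply(hetero$residual_sd, bins, median))
  expect_equal(tr2$by_mean$y, oracle)
  expect_error(residual_sd_trend(homo[1:5, ]),
               class = "beadnorm_validation_error")
})

test_that("replicate scatter statistics react to duplication and shifts", {
  design <- sample_design(tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    group = c("a", "a", "b", "b"), replicate = c(1, 2, 1, 2)))
  set.seed(56)
  base <- rnorm(200, 8)
  m <- cbind(a1 = base, a2 = base, b1 = base, b2 = base + 0.5)
  rs <- replicate_scatter_metrics(m, design)
  a_row <- rs$pairs[rs$pairs$group == "a", ]
  expect_equal(a_row$symmetry, 0)
  expect_equal(a_row$spread, 0)
  b_row <- rs$pairs[rs$pairs$group == "b", ]
  expect_equal(b_row$symmetry, 0.5)
  expect_equal(b_row$spread, 0.5)
  # exchanging the pair flips the sign of the shift only
  m2 <- cbind(a1 = base, a2 = base, b1 = base + 0.5, b2 = base)
  rs2 <- replicate_scatter_metrics(m2, design)
  expect_equal(rs2$pairs$symmetry[rs2$pairs$group == "b"], -0.5)
  expect_equal(rs2$pairs$spread, rs$pairs$spread)
})

test_that("pseudo-ROC identities: perfect separation, Mann-Whitney, null", {
  p <- setNames(c(rep(0, 10), rep(1, 200)), sprintf("p%03d", 1:210))
  tp <- names(p)[1:10]
  roc <- pseudo_roc(p, tp, tn_sample_size = 100, seed = 5)
  expect_equal(roc$auc, 1.0)
  expect_true(all(diff(roc$curve$fpr) >= 0))
  expect_true(all(diff(roc$curve$tpr) >= 0))
  # AUC == normalized Mann-Whitney statistic, including ties
  set.seed(57)
  for (i in 1:20) {
    pv <- setNames(round(runif(120), 2), sprintf("q%03d", 1:120))
    tp_i <- names(pv)[1:15]
    r <- pseudo_roc(pv, tp_i, tn_sample_size = 80, seed = i)
    w <- sum(rank(c(pv[r$tn_set], pv[tp_i]))[seq_len(80)]) - 80 * 81 / 2
    expect_equal(r$auc, w / (80 * 15), tolerance = 1e-12)
  }
  # null data: AUC near 1/2
  set.seed(58)
  aucs <- replicate(20, {
    pv <- setNames(runif(500), sprintf("r%03d", 1:500))
    pseudo_roc(pv, names(pv)[1:20], seed = sample.int(1e6, 1))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # reproducible TN sampling
  expect_identical(pseudo_roc(p, tp, seed = 9)$tn_set,
                   pseudo_roc(p, tp, seed = 9)$tn_set)
  expect_error(pseudo_roc(p, tp, tn_sample_size = 1e6),
               class = "beadnorm_validation_error")
})

test_that("orthogonal regression recovers noiseless lines and beats OLS orthogonally", {
  x <- seq(-3, 3, length.out = 25)
  fit <- orthogonal_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$objective, 0, tolerance = 1e-20)
  # swapping axes inverts the slope for noiseless data
  fit_sw <- orthogonal_regression(2 * x + 1, x)
  expect_equal(fit_sw$slope, 1 / 2, tolerance = 1e-12)
  set.seed(59)
  y <- 0.8 * x + rnorm(25, 0, 0.6)
  fit2 <- orthogonal_regression(x, y)
  ortho_obj <- function(sl, ic) sum((y - ic - sl * x)^2 / (1 + sl^2))
  # objective no worse than the OLS line measured orthogonally
  ols <- coef(lm(y ~ x))
  expect_lte(fit2$objective, ortho_obj(ols[2], ols[1]))
  # and matches a fine grid search around the fit
  grid <- expand.grid(sl = seq(fit2$slope - 0.2, fit2$slope + 0.2, 0.0005),
                      ic = seq(fit2$intercept - 0.2, fit2$intercept + 0.2,
                               0.0005))
  best <- min(mapply(ortho_obj, grid$sl, grid$ic))
  expect_lt(fit2$objective - best, 1e-6)
  expect_error(orthogonal_regression(rep(1, 5), rep(2, 5)),
               class = "beadnorm_validation_error")
})

test_that("correlation scores reproduce the printed cut-offs", {
  expect_equal(correlation_score(c(1, 0.97, 0.96)), c(2L, 2L, 2L))
  expect_equal(correlation_score(0.95), 1L)
  expect_equal(correlation_score(c(0.94, 0.93, 0.92)), c(1L, 0L, 0L))
  expect_equal(correlation_score(0.91), -1L)
  expect_equal(correlation_score(c(0.9, 0.85, -1)), c(-2L, -2L, -2L))
})

test_that("fc_correlation pools pairs and matches the textbook formula", {
  set.seed(60)
  ref <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:8), each = 3),
    comparison = rep(c("c1", "c2", "c3"), 8),
    log2_ratio = rnorm(24, 0, 1.2))
  pf <- dplyr::mutate(ref, pipeline_log2_ratio = log2_ratio * 0.9 +
                        rnorm(24, 0, 0.1))
  res <- fc_correlation(pf)
  num <- sum((pf$log2_ratio - mean(pf$log2_ratio)) *
               (pf$pipeline_log2_ratio - mean(pf$pipeline_log2_ratio)))
  den <- sqrt(sum((pf$log2_ratio - mean(pf$log2_ratio))^2) *
                sum((pf$pipeline_log2_ratio -
                       mean(pf$pipeline_log2_ratio))^2))
  expect_equal(res$pearson_r, num / den, tolerance = 1e-14)
  expect_equal(res$n, 24)
  ident <- dplyr::mutate(ref, pipeline_log2_ratio = log2_ratio)
  expect_equal(fc_correlation(ident)$pearson_r, 1)
  expect_equal(fc_correlation(ident)$score, 2L)
})

test_that("AUC binning allocates 5/18/2 with deterministic tie handling", {
  set.seed(61)
  auc <- setNames(runif(25, 0.8, 0.95), enumerate_pipelines()$name)
  sc <- auc_bin_scores(auc)
  expect_equal(as.integer(table(factor(sc, levels = -1:1))), c(5L, 18L, 2L))
  expect_equal(names(sort(auc))[1:5], names(sc)[match(names(sort(auc))[1:5], names(sc))])
  expect_true(all(sc[names(sort(auc))[1:5]] == -1L))
  expect_true(all(sc[names(sort(auc))[24:25]] == 1L))
  # permuting the input leaves per-pipeline scores unchanged
  perm <- sample(25)
  expect_equal(auc_bin_scores(auc[perm])[names(auc)], sc[names(auc)])
  # all-equal values: ties broken lexicographically by name
  eq <- setNames(rep(0.9, 25), enumerate_pipelines()$name)
  sc_eq <- auc_bin_scores(eq)
  expect_equal(unname(sc_eq[sort(names(eq))[1:5]]), rep(-1L, 5))
  expect_equal(unname(sc_eq[sort(names(eq))[24:25]]), rep(1L, 2))
  expect_error(auc_bin_scores(eq[1:10]), class = "beadnorm_validation_error")
})

test_that("slope binning is monotone with configurable cut points", {
  cuts <- c(0.55, 0.65, 0.75, 0.9)
  sl <- c(a = 0.96, b = 0.5, c = 0.6, d = 0.7, e = 0.8)
  sc <- slope_bin_scores(sl, cuts)
  expect_equal(unname(sc), c(2L, -2L, -1L, 0L, 1L))
  shuffled <- sort(runif(30, 0.3, 1.1))
  expect_true(all(diff(slope_bin_scores(setNames(shuffled,
                                                 paste0("p", 1:30)), cuts)) >= 0))
  expect_error(slope_bin_scores(sl, c(0.5, 0.4, 0.6, 0.7)),
               class = "beadnorm_validation_error")
})

test_that("aggregate_scores sums rows, ranks, and clusters deterministically", {
  sc <- tidyr::expand_grid(pipeline = c("pipeA", "pipeB", "pipeC"),
                           measure = c("m1", "m2", "m3"))
  sc$score <- c(2L, 1L, -1L,  0L, 0L, 0L,  2L, 1L, -1L)
  ev <- aggregate_scores(sc)
  expect_equal(unname(ev$row_sums), c(2L, 0L, 2L))
  expect_equal(ev$ranking$pipeline, c("pipeA", "pipeC", "pipeB"))
  # identical rows merge first in the Manhattan/complete clustering
  hc <- hclust(dist(ev$scores, method = "manhattan"), method = "complete")
  expect_equal(sort(hc$merge[1, ]), c(-3, -1))
  # measure order is irrelevant to the sums
  ev2 <- aggregate_scores(sc[sample(nrow(sc)), ])
  expect_equal(ev2$row_sums[names(ev$row_sums)], ev$row_sums)
  expect_error(aggregate_scores(dplyr::bind_rows(sc, sc[1, ])),
               class = "beadnorm_validation_error")
  # missing cells become 0 with a warning
  expect_warning(ev3 <- aggregate_scores(sc[-1, ]), "missing")
  expect_equal(unname(ev3$row_sums["pipeA"]), 0L)
  # manual overrides replace cells
  ov <- tibble::tibble(pipeline = "pipeB", measure = "m1", score = 2L)
  ev4 <- aggregate_scores(sc, manual_overrides = ov)
  expect_equal(unname(ev4$row_sums["pipeB"]), 2L)
})
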
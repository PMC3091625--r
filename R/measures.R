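#' Empirical CDF of FDR-adjusted F-test p-values
#'
#' Evaluates the right-continuous empirical distribution function of
#' `p_adj` on a fixed cutoff grid that always contains the two highlighted
#' working cutoffs 0.02 and 0.05.
#'
#' @param anova An ANOVA tibble from [f_test()].
#' @param n_grid Number of equally spaced grid points on \[0, 1\].
#' @return A tibble with columns `cutoff` and `fraction`.
#' @export
fstat_cdf <- function(anova, n_grid = 512) {
  if (!nrow(anova)) {
    abort("empty ANOVA table", class = "beadnorm_validation_error")
  }
  grid <- sort(unique(c(seq(0, 1, length.out = n_grid), 0.02, 0.05)))
  fn <- ecdf(anova$p_adj)
  tibble::tibble(cutoff = grid, fraction = fn(grid))
}

fit_trend <- function(x, y, span = 0.5) {
  fit <- lowess(x, y, f = span)
  approx(fit$x, fit$y, xout = x, rule = 2, ties = "ordered")$y
}

#' Significance versus between-group variability
#'
#' Restricts to probes with `msq_between` at or below a cap (default 5, the
#' region where the relationship is diagnostic), fits a local-regression
#' trend of `-log10(p)` on `msq_between`, and summarizes the scatter around
#' the trend (median absolute residual) together with the fraction of
#' points that combine low between-group variability with high
#' significance — the signature of methods that overstate evidence for
#' barely-varying probes.
#'
#' @param anova An ANOVA tibble from [f_test()].
#' @param msq_cap Include probes with `msq_between <= msq_cap`.
#' @param low_msq,high_neglog Thresholds defining the flagged corner:
#'   `msq_between < low_msq` and `-log10(p) > high_neglog`.
#' @param span Trend smoother span.
#' @return A list of class `pvalue_msq_summary`: `points` (tibble with
#'   trend), `dispersion`, `flagged_fraction`.
#' @export
pvalue_vs_msq <- function(anova, msq_cap = 5, low_msq = 1, high_neglog = 2,
                          span = 0.5) {
  if (msq_cap <= 0) {
    abort("msq_cap must be positive", class = "beadnorm_validation_error")
  }
  keep <- is.finite(anova$p) & anova$p > 0 & anova$msq_between <= msq_cap
  pts <- anova[keep, c("probe_id", "msq_between", "p")]
  if (nrow(pts) < 10) {
    abort("fewer than 10 probes under the msq cap",
          class = "beadnorm_validation_error")
  }
  pts$neglog_p <- -log10(pts$p)
  pts$trend <- fit_trend(pts$msq_between, pts$neglog_p, span)
  resid <- pts$neglog_p - pts$trend
  structure(list(
    points = tibble::as_tibble(pts),
    dispersion = median(abs(resid)),
    flagged_fraction = mean(pts$msq_between < low_msq &
                              pts$neglog_p > high_neglog)),
    class = "pvalue_msq_summary")
}

# count local maxima of a kernel density estimate, ignoring bumps below
# `min_rel` of the global maximum
density_mode_count <- function(x, min_rel = 0.01) {
  d <- density(x, bw = "nrd0", n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  sum(y[peaks] >= min_rel * max(y))
}

#' Distribution summaries of the ANOVA mean squares
#'
#' Summarizes `msq_between` and `msq_within` (quartiles, IQR), counts the
#' `msq_within` values exceeding an artificial benchmark `msq_between`
#' computed from stated group means (default means (6, 6, 7) of four
#' replicates each, giving 4/3), and counts the modes of a kernel density
#' estimate of each mean square to flag bimodal within-group variability.
#'
#' @param anova An ANOVA tibble from [f_test()].
#' @param benchmark_group_means Group means defining the benchmark.
#' @param benchmark_n Replicates per benchmark group.
#' @return A list of class `msq_summary`: `benchmark_msq`, `quartiles`
#'   (tibble), `n_within_above_benchmark`, `mode_count_within`,
#'   `mode_count_between`.
#' @export
msq_summaries <- function(anova, benchmark_group_means = c(6, 6, 7),
                          benchmark_n = 4) {
  bench <- group_msq(lapply(benchmark_group_means, rep, times = benchmark_n))
  qs <- function(v) quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- qs(anova$msq_between)
  qw <- qs(anova$msq_within)
  structure(list(
    benchmark_msq = unname(bench["msq_between"]),
    quartiles = tibble::tibble(
      statistic = rep(c("msq_between", "msq_within"), each = 3),
      quartile = rep(c(0.25, 0.5, 0.75), 2),
      value = c(qb, qw)),
    iqr = c(msq_between = qb[3] - qb[1], msq_within = qw[3] - qw[1]),
    n_within_above_benchmark = sum(anova$msq_within >
                                     unname(bench["msq_between"])),
    mode_count_within = density_mode_count(anova$msq_within),
    mode_count_between = density_mode_count(anova$msq_between)),
    class = "msq_summary")
}

#' Volcano-plot summary statistics
#'
#' Per comparison, fits a local-regression trend of `-log10(p)` on the
#' log2 ratio, reports the scatter around the trend and an asymmetry
#' statistic: the mean absolute difference between the trend evaluated at
#' mirrored positive and negative ratios (0 for a symmetric volcano).
#'
#' @param modt A moderated-t tibble from [moderated_t()].
#' @param span Trend smoother span.
#' @return A tibble with one row per comparison: `comparison`,
#'   `dispersion`, `asymmetry`; trend points in the `trend` list-column.
#' @export
volcano_summary <- function(modt, span = 0.5) {
  dplyr::group_by(modt, .data$comparison) |>
    dplyr::group_map(function(df, key) {
      if (sd(df$log2_ratio) == 0) {
        abort("constant log2 ratios; volcano undefined",
              class = "beadnorm_validation_error")
      }
      keep <- is.finite(df$p) & df$p > 0
      x <- df$log2_ratio[keep]
      y <- -log10(df$p[keep])
      trend <- fit_trend(x, y, span)
      fit <- lowess(x, y, f = span)
      tf <- approxfun(fit$x, fit$y, rule = 2, ties = "ordered")
      r <- seq(0, min(max(x), -min(x)), length.out = 101)[-1]
      asym <- if (length(r)) mean(abs(tf(r) - tf(-r))) else NA_real_
      tibble::tibble(comparison = key$comparison,
                     dispersion = median(abs(y - trend)),
                     asymmetry = asym,
                     trend = list(tibble::tibble(log2_ratio = x,
                                                 neglog_p = y,
                                                 trend = trend)))
    }) |>
    dplyr::bind_rows()
}

binned_medians <- function(x, y, n_bins = 10) {
  if (diff(range(x)) == 0) {
    abort("degenerate intensity range", class = "beadnorm_validation_error")
  }
  bins <- cut(rank(x, ties.method = "first"), breaks = n_bins, labels = FALSE)
  tibble::tibble(bin = sort(unique(bins)),
                 x = as.numeric(tapply(x, bins, median)),
                 y = as.numeric(tapply(y, bins, median)))
}

#' Intensity dependence of the residual standard deviation
#'
#' Bins probes by mean and by minimum expression, takes the median residual
#' SD per bin, and reports a flatness statistic per axis: the ratio of the
#' largest to the smallest binned median SD. A value near 1 means the
#' variance is stable across the intensity range — the behaviour a good
#' variance-stabilizing pre-processing should deliver.
#'
#' @param sd_table Output of [residual_sd()].
#' @param n_bins Number of intensity bins.
#' @return A list of class `sd_trend`: `by_mean`, `by_min` (binned-median
#'   tibbles) and `flatness` (named vector, one entry per axis).
#' @export
residual_sd_trend <- function(sd_table, n_bins = 10) {
  if (nrow(sd_table) < 20) {
    abort("need at least 20 probes", class = "beadnorm_validation_error")
  }
  by_mean <- binned_medians(sd_table$mean_expr, sd_table$residual_sd, n_bins)
  by_min <- binned_medians(sd_table$min_expr, sd_table$residual_sd, n_bins)
  flat <- function(b) {
    lo <- min(b$y)
    if (lo <= 0) lo <- max(min(b$y[b$y > 0], na.rm = TRUE) / 2, 1e-12)
    max(b$y) / lo
  }
  structure(list(by_mean = by_mean, by_min = by_min,
                 flatness = c(mean = flat(by_mean), min = flat(by_min))),
            class = "sd_trend")
}

#' Replicate-pair scatter symmetry and spread
#'
#' For every pair of replicate arrays within a group, summarizes the
#' scatter about the identity diagonal: the signed median of pairwise
#' differences (systematic shift of one replicate against the other) and
#' the median absolute pairwise difference (spread). Aggregates over pairs
#' per group and overall.
#'
#' @param m Probe x sample matrix on a log2-like scale.
#' @param design A design tibble.
#' @return A list of class `replicate_scatter`: `pairs` (per-pair tibble)
#'   and `aggregate` (overall medians of |symmetry| and spread).
#' @export
replicate_scatter_metrics <- function(m, design) {
  m <- as.matrix(m)
  by_group <- split_by_group(m, design)
  by_group <- by_group[lengths(by_group) >= 2]
  if (!length(by_group)) {
    abort("no group with >= 2 replicates", class = "beadnorm_validation_error")
  }
  pairs <- purrr::map_dfr(names(by_group), function(g) {
    s <- by_group[[g]]
    combos <- utils::combn(s, 2, simplify = FALSE)
    purrr::map_dfr(combos, function(pr) {
      d <- m[, pr[2]] - m[, pr[1]]
      tibble::tibble(group = g, sample_a = pr[1], sample_b = pr[2],
                     symmetry = median(d), spread = median(abs(d)))
    })
  })
  structure(list(
    pairs = pairs,
    aggregate = c(abs_symmetry = median(abs(pairs$symmetry)),
                  spread = median(pairs$spread))),
    class = "replicate_scatter")
}

#' Pseudo-ROC curve from adjusted p-values
#'
#' True positives are the designated TP probes; true negatives are sampled
#' (seeded, reproducible) from the remaining probes. Sweeping the observed
#' adjusted p-values as thresholds gives the true- and false-positive rates
#' whose trapezoid area is the AUC; it coincides exactly with the
#' normalized Mann-Whitney rank-sum statistic on the two p-value sets.
#'
#' @param p_adj Named numeric vector of adjusted p-values (names = probes).
#' @param tp_set Character vector of true-positive probe ids.
#' @param tn_sample_size Number of presumed true negatives to sample;
#'   default 20 per TP.
#' @param seed Integer seed for the TN sampling.
#' @return A list of class `roc_curve`: `curve` (tibble with `threshold`,
#'   `fpr`, `tpr`), `auc`, `tp_set`, `tn_set`.
#' @export
pseudo_roc <- function(p_adj, tp_set, tn_sample_size = 20 * length(tp_set),
                       seed = 1L) {
  if (!length(tp_set)) {
    abort("tp_set must be non-empty", class = "beadnorm_validation_error")
  }
  if (is.null(names(p_adj))) {
    abort("p_adj must be named by probe", class = "beadnorm_validation_error")
  }
  miss <- setdiff(tp_set, names(p_adj))
  if (length(miss)) {
    abort(paste0("TP probe(s) without p-values: ", paste(miss, collapse = ", ")),
          class = "beadnorm_validation_error")
  }
  pool <- setdiff(names(p_adj), tp_set)
  if (tn_sample_size > length(pool)) {
    abort("tn_sample_size exceeds the non-TP pool",
          class = "beadnorm_validation_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  tn_set <- sample(pool, tn_sample_size)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  p_tp <- p_adj[tp_set]
  p_tn <- p_adj[tn_set]
  thr <- sort(unique(c(-Inf, p_adj[c(tp_set, tn_set)], Inf)))
  tpr <- vapply(thr, function(t) mean(p_tp <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(p_tn <= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(curve = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, tp_set = tp_set, tn_set = tn_set),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC = ", format(x$auc, digits = 4), " (",
      length(x$tp_set), " TP, ", length(x$tn_set), " TN)\n", sep = "")
  invisible(x)
}

#' Orthogonal (total least squares) regression
#'
#' Fits the line minimizing the summed squared Euclidean (perpendicular)
#' distances of the points to the line: the slope is the direction of the
#' first principal axis of the centered point cloud, the intercept follows
#' from the centroid. Used to quantify fold-change bias of a pipeline
#' against reference (qRT-PCR-like) log2 ratios: a slope below 1 means
#' compressed fold changes, an intercept below/above 0 an under-/
#' over-estimation.
#'
#' @param x Reference log2 ratios.
#' @param y Pipeline log2 ratios.
#' @return An object of class `ortho_fit`: `slope`, `intercept`,
#'   `residuals` (signed orthogonal distances), `objective`, `n`.
#' @export
orthogonal_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("need at least 3 points", class = "beadnorm_validation_error")
  }
  if (var(x) == 0 && var(y) == 0) {
    abort("zero variance in both coordinates",
          class = "beadnorm_validation_error")
  }
  pc <- prcomp(cbind(x, y), center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  if (abs(v[1]) < .Machine$double.eps) {
    abort("first principal axis is vertical; slope undefined",
          class = "beadnorm_validation_error")
  }
  slope <- v[2] / v[1]
  intercept <- mean(y) - slope * mean(x)
  resid <- (y - (intercept + slope * x)) / sqrt(1 + slope^2)
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 residuals = resid, objective = sum(resid^2),
                 n = length(x)),
            class = "ortho_fit")
}

#' @export
print.ortho_fit <- function(x, ...) {
  cat("<ortho_fit> slope = ", format(x$slope, digits = 4),
      ", intercept = ", format(x$intercept, digits = 4),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Fold changes of a pipeline matrix for the reference panel
#'
#' Computes, for every (gene, comparison) pair of a reference table, the
#' pipeline's log2 ratio (difference of group means of the mapped probe).
#'
#' @param m Probe x sample matrix on a log2-like scale.
#' @param design A design tibble.
#' @param reference A [reference_fold_changes()] tibble.
#' @param probe_map Optional tibble (`probe_id`, `gene_id`); by default
#'   gene ids are taken to be probe ids.
#' @return The reference tibble with an added `pipeline_log2_ratio` column.
#' @export
pipeline_fold_changes <- function(m, design, reference, probe_map = NULL) {
  m <- as.matrix(m)
  by_group <- split_by_group(m, design)
  gm <- vapply(by_group, function(s) rowMeans(m[, s, drop = FALSE]),
               numeric(nrow(m)))
  rownames(gm) <- rownames(m)
  map <- if (is.null(probe_map)) {
    setNames(rownames(m), rownames(m))
  } else {
    setNames(probe_map$probe_id, probe_map$gene_id)
  }
  miss <- setdiff(unique(reference$gene_id), names(map))
  if (length(miss)) {
    abort(paste0("unmatched gene(s): ", paste(miss, collapse = ", ")),
          class = "beadnorm_validation_error")
  }
  probe <- map[reference$gene_id]
  parsed <- t(vapply(reference$comparison, parse_comparison, character(2)))
  reference$pipeline_log2_ratio <-
    gm[cbind(probe, parsed[, 2])] - gm[cbind(probe, parsed[, 1])]
  reference
}
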
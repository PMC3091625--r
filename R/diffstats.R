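#' Between- and within-group mean squares for one probe
#'
#' The one-way ANOVA decomposition: with k groups of sizes n_i, group means
#' x-bar_i and grand mean x-bar over N observations,
#' `msq_between = sum_i n_i (xbar_i - xbar)^2 / (k - 1)` and
#' `msq_within = sum_ij (x_ij - xbar_i)^2 / (N - k)`. Their ratio follows an
#' F distribution with (k - 1, N - k) degrees of freedom under the null.
#'
#' @param values_by_group List of numeric vectors, one per group.
#' @return Named numeric vector with `msq_between` and `msq_within`.
#' @export
group_msq <- function(values_by_group) {
  k <- length(values_by_group)
  if (k < 2) {
    abort("need at least two groups", class = "beadnorm_validation_error")
  }
  n_i <- lengths(values_by_group)
  if (any(n_i == 0)) {
    abort("every group must be non-empty", class = "beadnorm_validation_error")
  }
  n_tot <- sum(n_i)
  means <- vapply(values_by_group, mean, numeric(1))
  grand <- sum(n_i * means) / n_tot
  msq_between <- sum(n_i * (means - grand)^2) / (k - 1)
  if (n_tot == k) {
    abort("no residual degrees of freedom (one observation per group)",
          class = "beadnorm_validation_error")
  }
  ssw <- sum(vapply(seq_len(k), function(i)
    sum((values_by_group[[i]] - means[i])^2), numeric(1)))
  c(msq_between = msq_between, msq_within = ssw / (n_tot - k))
}

split_by_group <- function(m, design, groups = NULL) {
  design <- sample_design(design)
  if (!is.null(groups)) design <- design[design$group %in% groups, ]
  miss <- setdiff(design$sample_id, colnames(m))
  if (length(miss)) {
    abort(paste0("design sample(s) absent from matrix: ",
                 paste(miss, collapse = ", ")),
          class = "beadnorm_validation_error")
  }
  split(design$sample_id, design$group)
}

#' Per-probe one-way ANOVA F-test
#'
#' Computes the mean-square decomposition of [group_msq()] for every probe,
#' the F statistic `msq_between / msq_within` with (k - 1, N - k) degrees of
#' freedom, its upper-tail p-value, and the Benjamini-Hochberg adjusted
#' p-value. Probes with zero within-group variance are retained: F is
#' infinite (p = 0) if there is any between-group spread, and p = 1 when
#' both mean squares vanish.
#'
#' @param m Probe x sample matrix on a log2-like scale.
#' @param design A design tibble (see [sample_design()]).
#' @param groups Optional subset of group labels to use.
#' @return A tibble with columns `probe_id`, `msq_between`, `msq_within`,
#'   `f_stat`, `df1`, `df2`, `p`, `p_adj`.
#' @export
f_test <- function(m, design, groups = NULL) {
  m <- as.matrix(m)
  by_group <- split_by_group(m, design, groups)
  k <- length(by_group)
  if (k < 2) {
    abort("need at least two groups", class = "beadnorm_validation_error")
  }
  n_i <- lengths(by_group)
  if (any(n_i < 2)) {
    abort("every group needs >= 2 samples for the F-test",
          class = "beadnorm_validation_error")
  }
  n_tot <- sum(n_i)
  gm <- vapply(by_group, function(s) rowMeans(m[, s, drop = FALSE]),
               numeric(nrow(m)))
  grand <- as.vector(gm %*% n_i) / n_tot
  ssb <- as.vector((gm - grand)^2 %*% n_i)
  ssw <- unname(rowSums(vapply(seq_len(k), function(i) {
    rowSums((m[, by_group[[i]], drop = FALSE] - gm[, i])^2)
  }, numeric(nrow(m)))))
  df1 <- k - 1L
  df2 <- n_tot - k
  msq_b <- ssb / df1
  msq_w <- ssw / df2
  f <- msq_b / msq_w
  p <- pf(f, df1, df2, lower.tail = FALSE)
  zero_w <- msq_w == 0
  f[zero_w & msq_b > 0] <- Inf
  p[zero_w & msq_b > 0] <- 0
  p[zero_w & msq_b == 0] <- 1
  f[zero_w & msq_b == 0] <- NA_real_
  tibble::tibble(
    probe_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    msq_between = msq_b, msq_within = msq_w, f_stat = f,
    df1 = df1, df2 = df2, p = p, p_adj = bh_adjust(p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: sort the p-values ascending, multiply by m/rank,
#' enforce monotone non-increasing cumulative minima from the largest rank
#' down, cap at 1, and restore the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "beadnorm_validation_error")
  }
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Newton solve of trigamma(y) = x, following the standard empirical-Bayes
# variance-shrinkage recipe.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Method-of-moments fit of the scaled inverse-chi-square prior on residual
# variances: returns prior df d0 and prior variance s0^2.
fit_variance_prior <- function(s2, df) {
  z <- log(s2[is.finite(log(s2))])
  if (length(z) < 3) return(list(d0 = 0, s0_sq = NA_real_, ok = FALSE))
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- var(e)
  excess <- ev - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq, ok = TRUE)
}

parse_comparison <- function(comp) {
  if (is.character(comp) && length(comp) == 1 && grepl("_vs_", comp)) {
    strsplit(comp, "_vs_", fixed = TRUE)[[1]][2:1]
  } else if (length(comp) == 2) {
    as.character(comp)[2:1]  # (treated, control) -> (control, treated)
  } else {
    abort("comparisons must be group pairs or '<a>_vs_<b>' strings",
          class = "beadnorm_validation_error")
  }
}

#' Empirical-Bayes moderated t-statistics for pairwise group comparisons
#'
#' Fits the per-probe group-means model, pools the residual variance
#' `s_g^2` over `d_g = N - k` degrees of freedom, estimates prior degrees of
#' freedom `d0` and prior variance `s0^2` by the method of moments on
#' `log s_g^2` across probes, and shrinks each probe's variance to the
#' posterior `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`. The moderated t for a
#' comparison a vs b is the log2 ratio divided by the posterior standard
#' error, with `d0 + d_g` degrees of freedom; with `d0 = 0` it reduces to
#' the ordinary t from the same fit, with `d0 = Inf` to full shrinkage
#' toward `s0`. Two-sided p-values are BH-adjusted per comparison.
#'
#' @param m Probe x sample matrix on a log2-like scale.
#' @param design A design tibble.
#' @param comparisons List of comparisons, each either `c(treated, control)`
#'   or a `"<treated>_vs_<control>"` string; default all pairwise
#'   comparisons in design order.
#' @param d0_override Optional fixed prior df (e.g. `0` or `Inf`) replacing
#'   the estimated `d0`.
#' @return A tibble with columns `probe_id`, `comparison`, `log2_ratio`,
#'   `moderated_t`, `p`, `p_adj`; prior hyperparameters are attached as
#'   attributes `d0` and `s0_sq`.
#' @export
moderated_t <- function(m, design, comparisons = NULL, d0_override = NULL) {
  m <- as.matrix(m)
  by_group <- split_by_group(m, design)
  n_i <- lengths(by_group)
  if (any(n_i < 2)) {
    abort("every compared group needs >= 2 samples",
          class = "beadnorm_validation_error")
  }
  labels <- names(by_group)
  if (is.null(comparisons)) {
    design_order <- unique(sample_design(design)$group)
    pairs <- utils::combn(design_order, 2, simplify = FALSE)
    comparisons <- lapply(pairs, function(pr) c(pr[2], pr[1]))
  }
  gm <- vapply(by_group, function(s) rowMeans(m[, s, drop = FALSE]),
               numeric(nrow(m)))
  k <- length(by_group)
  d_g <- sum(n_i) - k
  ssw <- unname(rowSums(vapply(seq_len(k), function(i) {
    rowSums((m[, by_group[[i]], drop = FALSE] - gm[, i])^2)
  }, numeric(nrow(m)))))
  s2 <- ssw / d_g
  prior <- fit_variance_prior(s2, d_g)
  if (!prior$ok) {
    warn("degenerate variance distribution; falling back to ordinary t (d0 = 0)")
    prior <- list(d0 = 0, s0_sq = 0)
  }
  d0 <- d0_override %||% prior$d0
  s0_sq <- prior$s0_sq
  s_tilde_sq <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + d_g * s2) / (d0 + d_g)
  }
  df_total <- if (is.infinite(d0)) Inf else d0 + d_g
  probe_id <- rownames(m) %||% as.character(seq_len(nrow(m)))
  res <- purrr::map_dfr(comparisons, function(comp) {
    ba <- parse_comparison(comp)  # (control, treated)
    ctrl <- ba[1]; trt <- ba[2]
    if (!all(c(ctrl, trt) %in% labels)) {
      abort(paste0("unknown group in comparison: ", trt, "_vs_", ctrl),
            class = "beadnorm_validation_error")
    }
    lev <- 1 / n_i[[trt]] + 1 / n_i[[ctrl]]
    ratio <- unname(gm[, trt] - gm[, ctrl])
    t_stat <- ratio / sqrt(s_tilde_sq * lev)
    p <- 2 * pt(abs(t_stat), df = df_total, lower.tail = FALSE)
    p[is.na(t_stat)] <- 1
    tibble::tibble(probe_id = probe_id,
                   comparison = paste0(trt, "_vs_", ctrl),
                   log2_ratio = ratio, moderated_t = t_stat,
                   p = p, p_adj = bh_adjust(p))
  })
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  res
}

#' Residual standard deviation of the group-means fit
#'
#' The residual SD per probe equals `sqrt(msq_within)` of the one-way
#' decomposition (algebraic identity), with `N - k` residual degrees of
#' freedom; the mean and minimum expression accompany it so the
#' intensity-dependence of the variance can be inspected.
#'
#' @inheritParams f_test
#' @return A tibble with `probe_id`, `residual_sd`, `mean_expr`, `min_expr`.
#' @export
residual_sd <- function(m, design, groups = NULL) {
  m <- as.matrix(m)
  an <- f_test(m, design, groups)
  used <- unlist(split_by_group(m, design, groups), use.names = FALSE)
  tibble::tibble(
    probe_id = an$probe_id,
    residual_sd = sqrt(an$msq_within),
    mean_expr = rowMeans(m[, used, drop = FALSE]),
    min_expr = apply(m[, used, drop = FALSE], 1, min))
}
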
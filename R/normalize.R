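# Monotone cubic map through anchor pairs, linear extrapolation outside the
# anchor range. Shared machinery for rsn, rank-invariant and cubic-spline
# normalization.
monotone_map <- function(xa, ya) {
  keep <- !duplicated(xa)
  xa <- xa[keep]
  ya <- cummax(ya[keep])
  o <- order(xa)
  xa <- xa[o]
  ya <- ya[o]
  if (length(xa) < 2) {
    abort("need at least two distinct anchors", class = "beadnorm_validation_error")
  }
  f <- splinefun(xa, ya, method = "monoH.FC")
  n <- length(xa)
  slope_lo <- (ya[2] - ya[1]) / (xa[2] - xa[1])
  slope_hi <- (ya[n] - ya[n - 1]) / (xa[n] - xa[n - 1])
  function(v) {
    out <- f(v)
    lo <- v < xa[1]
    hi <- v > xa[n]
    out[lo] <- ya[1] + slope_lo * (v[lo] - xa[1])
    out[hi] <- ya[n] + slope_hi * (v[hi] - xa[n])
    out
  }
}

#' Quantile normalization
#'
#' Classic sorted-mean substitution: the reference distribution is the mean
#' of the column-wise sorted values, and each column's values are replaced
#' by the reference value of their rank. Ties within a column receive the
#' mean of the reference slots the tie group spans, so the procedure is
#' deterministic and idempotent. Afterwards every column carries the same
#' multiset of values.
#'
#' @param m Numeric matrix with at least two columns.
#' @return Normalized matrix.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) {
    abort("quantile normalization needs >= 2 columns",
          class = "beadnorm_validation_error")
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    sv <- m[o, j]
    grp <- cumsum(c(TRUE, diff(sv) != 0))
    out[o, j] <- stats::ave(ref, grp)
  }
  out
}

#' Robust spline normalization (rsn)
#'
#' Combines quantile-style distribution matching with a continuous mapping:
#' the reference array is the one whose median is the median of the column
#' medians, and every other array is mapped onto it through a monotone cubic
#' spline fitted to matched quantile anchors. The mapping is continuous and
#' rank-preserving within each column.
#'
#' @param m Numeric matrix (transformed scale) with >= 2 columns.
#' @param n_anchors Number of quantile anchors for the spline fit.
#' @return Normalized matrix.
#' @export
rsn_normalize <- function(m, n_anchors = 200) {
  m <- as.matrix(m)
  if (ncol(m) < 2) {
    abort("rsn needs >= 2 columns", class = "beadnorm_validation_error")
  }
  meds <- apply(m, 2, median)
  ref_j <- which.min(abs(meds - median(meds)))
  probs <- seq(0, 1, length.out = min(n_anchors, nrow(m)))
  qr <- quantile(m[, ref_j], probs, names = FALSE)
  out <- m
  for (j in seq_len(ncol(m))) {
    if (j == ref_j) next
    qx <- quantile(m[, j], probs, names = FALSE)
    out[, j] <- monotone_map(qx, qr)(m[, j])
  }
  out
}

#' Loess normalization against a row-mean pseudo-reference
#'
#' For each array, the difference `M` to the row-mean pseudo-reference is
#' regressed on the average intensity `A = (column + rowmean)/2` with a
#' local regression smoother and the fitted intensity-dependent trend is
#' subtracted. One refinement pass (recomputing the pseudo-reference) is
#' applied after the first sweep.
#'
#' @param m Numeric matrix (transformed scale) with >= 2 columns.
#' @param span Smoother span.
#' @param iterations Total number of sweeps (1 sweep + 1 refinement).
#' @return Normalized matrix.
#' @export
loess_normalize <- function(m, span = 0.4, iterations = 2) {
  m <- as.matrix(m)
  if (ncol(m) < 2) {
    abort("loess normalization needs >= 2 columns",
          class = "beadnorm_validation_error")
  }
  if (nrow(m) < 10) {
    abort("too few probes for the loess smoother",
          class = "beadnorm_validation_error")
  }
  for (it in seq_len(iterations)) {
    ref <- rowMeans(m)
    for (j in seq_len(ncol(m))) {
      a <- (m[, j] + ref) / 2
      mm <- m[, j] - ref
      fit <- lowess(a, mm, f = span)
      trend <- approx(fit$x, fit$y, xout = a, rule = 2, ties = "ordered")$y
      m[, j] <- m[, j] - trend
    }
  }
  m
}

#' Variance stabilization and normalization (vsn-style)
#'
#' Jointly calibrates arrays with per-sample affine parameters (offset
#' `a_j`, scale `b_j > 0`) and applies a generalized-log transform
#' `h_j(x) = asinh((x - a_j) / b_j) / log(2)`, which behaves like `log2` at
#' high intensities and is finite for negative inputs. Parameters are
#' fitted by a simplified robust profile likelihood: minimize
#' `(n p / 2) log(RSS) - sum(log h')` where RSS are the squared deviations
#' of the transformed values from their probe means and the log-Jacobian
#' term calibrates the transform scale (without it the objective would
#' collapse by shrinking every array). Robustness comes from trimming the
#' fraction of probes with the largest deviation sums from both terms. The
#' fit is quasi-Newton with a fixed iteration cap and is deterministic
#' given data and settings.
#'
#' @param m Numeric raw-scale matrix (negatives allowed), >= 2 columns.
#' @param trim Fraction of the largest-deviation probes trimmed from the
#'   objective.
#' @param maxit Iteration cap of the optimizer.
#' @param tol Relative convergence tolerance on the objective.
#' @return Matrix on a log2-like (generalized-log) scale.
#' @export
vsn_normalize <- function(m, trim = 0.1, maxit = 50, tol = 1e-8) {
  m <- as.matrix(m)
  p <- ncol(m)
  n <- nrow(m)
  if (p < 2) {
    abort("vsn needs >= 2 columns", class = "beadnorm_validation_error")
  }
  # offsets start near the low quantile (the additive background), glog
  # scales at the spread of the dim probes
  a0 <- apply(m, 2, quantile, 0.05, names = FALSE)
  b0 <- vapply(seq_len(p), function(j) {
    lo <- m[, j][m[, j] <= quantile(m[, j], 0.3)]
    b <- mad(lo)
    if (!is.finite(b) || b <= 0) b <- sd(m[, j]) / 10
    max(b, .Machine$double.eps)
  }, numeric(1))
  n_keep <- max(1L, floor((1 - trim) * n))
  objective <- function(par) {
    a <- par[seq_len(p)]
    b <- exp(par[p + seq_len(p)])
    z <- sweep(sweep(m, 2, a, `-`), 2, b, `/`)
    h <- asinh(z)
    dev <- h - rowMeans(h)
    row_ss <- rowSums(dev * dev)
    keep <- order(row_ss)[seq_len(n_keep)]
    rss <- max(sum(row_ss[keep]), n_keep * p * 1e-12)  # floor: identical arrays
    # log h' = -log(b) - log(sqrt(z^2 + 1)), summed over the kept probes
    log_jac <- -n_keep * sum(log(b)) -
      0.5 * sum(log1p(z[keep, , drop = FALSE]^2))
    (n_keep * p / 2) * log(rss / (n_keep * p)) - log_jac
  }
  fit <- optim(c(a0, log(b0)), objective, method = "BFGS",
               control = list(maxit = maxit, reltol = tol))
  if (!is.finite(fit$value)) {
    abort(paste0("vsn fit did not converge; objective = ", fit$value),
          class = "beadnorm_validation_error")
  }
  a <- fit$par[seq_len(p)]
  b <- exp(fit$par[p + seq_len(p)])
  out <- asinh(sweep(sweep(m, 2, a, `-`), 2, b, `/`)) / log(2)
  dimnames(out) <- dimnames(m)
  attr(out, "vsn_params") <- tibble::tibble(
    sample_id = colnames(m) %||% as.character(seq_len(p)),
    offset = a, scale = b)
  out
}

#' Average normalization (global scaling)
#'
#' Scales each array so its mean intensity equals the grand mean of the
#' array means; the BeadStudio-style scaling normalization on the original
#' intensity scale.
#'
#' @param m Raw-scale matrix with positive column means.
#' @return Scaled matrix.
#' @export
average_normalize <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  if (any(mu <= 0)) {
    abort(paste0("non-positive column mean for sample ",
                 (colnames(m) %||% seq_len(ncol(m)))[which(mu <= 0)[1]]),
          class = "beadnorm_validation_error")
  }
  sweep(m, 2, mean(mu) / mu, `*`)
}

#' Rank-invariant normalization
#'
#' Selects, per array, the probes whose intensity rank stays within a
#' tolerance of their rank on a reference array (the one whose mean is
#' closest to the grand mean), restricted to a mid-intensity rank window,
#' fits a monotone smooth of reference vs array intensities on that
#' rank-invariant set, and maps all probes through it.
#'
#' @param m Raw-scale matrix, >= 2 columns.
#' @param rank_tol Maximum rank difference as a fraction of the probe count.
#' @param window Rank-fraction window (low, high) defining mid intensities.
#' @param min_set Minimum usable invariant-set size.
#' @param span Smoother span for the fitted mapping.
#' @return Normalized matrix.
#' @export
rank_invariant_normalize <- function(m, rank_tol = 0.05,
                                     window = c(0.05, 0.95),
                                     min_set = 10, span = 0.3) {
  m <- as.matrix(m)
  if (ncol(m) < 2) {
    abort("rank-invariant normalization needs >= 2 columns",
          class = "beadnorm_validation_error")
  }
  n <- nrow(m)
  mu <- colMeans(m)
  ref_j <- which.min(abs(mu - mean(mu)))
  r_ref <- rank(m[, ref_j], ties.method = "average")
  out <- m
  for (j in seq_len(ncol(m))) {
    if (j == ref_j) next
    r_j <- rank(m[, j], ties.method = "average")
    sel <- abs(r_j - r_ref) < rank_tol * n &
      r_ref >= window[1] * n & r_ref <= window[2] * n
    if (sum(sel) < min_set) {
      abort(paste0("rank-invariant set too small (", sum(sel), " probes) ",
                   "for sample ", (colnames(m) %||% seq_len(ncol(m)))[j],
                   "; increase rank_tol"),
            class = "beadnorm_validation_error")
    }
    fit <- lowess(m[sel, j], m[sel, ref_j], f = span)
    out[, j] <- monotone_map(fit$x, fit$y)(m[, j])
  }
  out
}

#' Cubic-spline normalization over matched quantile anchors
#'
#' Computes `n_anchors` quantile anchors per array (equally spaced in
#' rank), forms reference anchors as the geometric mean of the arrays'
#' anchors (arithmetic mean if any anchor is non-positive), and maps each
#' array through a monotone interpolating cubic spline from its anchors to
#' the reference anchors, with linear extrapolation outside the anchor
#' range.
#'
#' @param m Raw-scale matrix.
#' @param n_anchors Number of quantile anchors (default 100).
#' @return Normalized matrix.
#' @export
cubic_spline_normalize <- function(m, n_anchors = 100) {
  m <- as.matrix(m)
  if (n_anchors > nrow(m)) {
    abort("n_anchors exceeds the probe count",
          class = "beadnorm_validation_error")
  }
  probs <- (seq_len(n_anchors) - 0.5) / n_anchors
  anchors <- apply(m, 2, quantile, probs = probs, names = FALSE)
  ref <- if (all(anchors > 0)) {
    exp(rowMeans(log(anchors)))
  } else {
    rowMeans(anchors)
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    out[, j] <- monotone_map(anchors[, j], ref)(m[, j])
  }
  out
}
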
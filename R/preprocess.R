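#' BeadStudio-style background subtraction
#'
#' Subtracts, per sample, the mean signal of that sample's negative-control
#' beads from every probe. The result routinely contains negative
#' intensities; these are retained (positivity is the job of the downstream
#' positivity fixes, and the variance-stabilizing methods handle negatives
#' natively).
#'
#' @param profile A [bead_profile()].
#' @param controls A matching [control_profile()].
#' @return A [bead_profile()] with background-subtracted `avg_signal`; all
#'   other components pass through unchanged.
#' @export
subtract_background <- function(profile, controls) {
  stopifnot(inherits(profile, "bead_profile"),
            inherits(controls, "control_profile"))
  missing_s <- setdiff(profile$sample_id, controls$sample_id)
  if (length(missing_s)) {
    abort(paste0("no negative controls for sample(s): ",
                 paste(missing_s, collapse = ", ")),
          class = "beadnorm_validation_error")
  }
  bg <- colMeans(controls$avg_signal[, profile$sample_id, drop = FALSE])
  out <- profile
  out$avg_signal <- sweep(profile$avg_signal, 2, bg, `-`)
  out
}

#' Global positivity shift (forcePos)
#'
#' If the global minimum of the matrix is below 1, adds `1 - min` to every
#' entry so the minimum becomes exactly 1; otherwise returns the input
#' unchanged. The shift is global, not per column, so every pairwise
#' difference between entries is preserved exactly and between-array
#' differences are left for the normalization stage to handle.
#'
#' @param m Numeric matrix (finite values).
#' @return Shifted matrix.
#' @export
force_positive <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) {
    abort("force_positive needs finite values", class = "beadnorm_validation_error")
  }
  mn <- min(m)
  if (mn < 1) m <- m + (1 - mn)
  m
}

#' Normal-exponential convolution background correction (RMA-style)
#'
#' Models each array's intensities as signal ~ Exponential(alpha) plus
#' additive noise ~ Normal(mu, sigma^2) and replaces every observation by
#' the posterior mean of the signal, which is strictly positive. Parameters
#' are estimated per array: `mu` as the mode of a kernel density estimate of
#' the intensities, `sigma` as the root mean square of deviations below the
#' mode, and `alpha` as the reciprocal mean excess above the mode.
#'
#' @param m Numeric matrix (finite values; negatives allowed).
#' @return Matrix of strictly positive background-corrected intensities.
#' @export
rma_background <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) {
    abort("rma_background needs finite values", class = "beadnorm_validation_error")
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- m[, j]
    if (length(unique(o)) < 3 || sd(o) == 0) {
      abort(paste0("degenerate (near-constant) intensity column: ",
                   colnames(m)[j] %||% j),
            class = "beadnorm_validation_error")
    }
    d <- density(o, n = 512)
    mu <- d$x[which.max(d$y)]
    below <- o[o < mu]
    sigma <- if (length(below)) sqrt(mean((below - mu)^2)) else mad(o)
    if (sigma <= 0) sigma <- mad(o) + .Machine$double.eps
    above <- o[o > mu]
    alpha <- 1 / max(mean(above - mu), .Machine$double.eps)
    a <- o - mu - sigma^2 * alpha
    z <- a / sigma
    # posterior mean of the exponential signal; log-scale Mills ratio for
    # numerical stability far into the left tail
    out[, j] <- a + sigma * exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
  }
  out
}

#' Elementwise log2 transformation
#'
#' Requires strictly positive entries; background-subtracted data must go
#' through a positivity fix first.
#'
#' @param m Numeric matrix.
#' @return `log2(m)`.
#' @export
log2_transform <- function(m) {
  m <- as.matrix(m)
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(paste0("non-positive entry at probe ",
                 rownames(m)[bad[1, 1]] %||% bad[1, 1], ", sample ",
                 colnames(m)[bad[1, 2]] %||% bad[1, 2],
                 "; apply a positivity fix first"),
          class = "beadnorm_validation_error")
  }
  log2(m)
}

#' Variance-stabilizing transformation from bead-level replicates
#'
#' Uses the within-array technical replication of beads to estimate, per
#' sample, the variance-mean model `v(u) = (c1*u + c2)^2 + c3` from the
#' bead-level variances (`bead_stderr^2 * n_beads`) by quadratic regression
#' on binned medians, then applies the induced arsinh-family transform
#' `asinh((c1*u + c2)/sqrt(c3)) / c1` rescaled so that at high intensities
#' the result agrees with `log2(u)` (arsinh grows like the logarithm).
#' Negative intensities are handled naturally; the transform is strictly
#' increasing on the whole real line.
#'
#' @param profile A [bead_profile()] carrying `bead_stderr` and `n_beads`.
#' @param signal Optional matrix to transform instead of
#'   `profile$avg_signal` (e.g. after background subtraction); the
#'   variance model is still estimated from the bead-level statistics.
#' @param n_bins Number of intensity bins for the robust variance fit.
#' @return Matrix on a log2-like scale.
#' @export
vst_transform <- function(profile, signal = NULL, n_bins = 50) {
  stopifnot(inherits(profile, "bead_profile"))
  if (is.null(profile$bead_stderr) || is.null(profile$n_beads)) {
    abort(paste0("vst needs bead_stderr and n_beads; for plain matrices ",
                 "use the log pipelines instead"),
          class = "beadnorm_validation_error")
  }
  x <- if (is.null(signal)) profile$avg_signal else as.matrix(signal)
  v_bead <- profile$bead_stderr^2 * profile$n_beads
  out <- x
  for (j in seq_len(ncol(x))) {
    u <- profile$avg_signal[, j]
    v <- v_bead[, j]
    bins <- cut(rank(u, ties.method = "first"),
                breaks = min(n_bins, max(3, floor(length(u) / 5))),
                labels = FALSE)
    bu <- tapply(u, bins, median)
    bv <- tapply(v, bins, median)
    fit <- stats::lm(bv ~ bu + I(bu^2))
    a2 <- max(stats::coef(fit)[[3]], 1e-10)
    c1 <- sqrt(a2)
    c2 <- stats::coef(fit)[[2]] / (2 * c1)
    c3 <- stats::coef(fit)[[1]] - c2^2
    if (!is.finite(c3) || c3 <= 0) c3 <- max(stats::coef(fit)[[1]], 1e-6)
    h <- asinh((c1 * x[, j] + c2) / sqrt(c3))
    # asinh(z) ~ log(2z): divide by log 2 and drop the gain so that
    # h(u) ~ log2(u) for large u
    out[, j] <- h / log(2) - log2(2 * c1 / sqrt(c3))
  }
  out
}
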
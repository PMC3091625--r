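#' Plot a pseudo-ROC curve
#'
#' @param object A `roc_curve` from [pseudo_roc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = paste0("AUC = ", format(object$auc, digits = 4))) +
    ggplot2::coord_equal()
}

#' Heatmap of the pipeline x measure quality scores
#'
#' Rows and columns follow the stored hierarchical-clustering orders
#' (Manhattan distance, complete linkage); row labels carry the score sums
#' used for the final ranking.
#'
#' @param object An `eval_matrix` from [aggregate_scores()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_matrix <- function(object, ...) {
  df <- tidy(object)
  rows <- rownames(object$scores)[object$row_order]
  cols <- colnames(object$scores)[object$col_order]
  labels <- paste0(rows, " (", object$row_sums[rows], ")")
  df$pipeline <- factor(df$pipeline, levels = rows, labels = labels)
  df$measure <- factor(df$measure, levels = cols)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$pipeline,
                                   fill = .data$score)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "forestgreen", limits = c(-2, 2)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' ECDF plot of FDR-adjusted F-test p-values
#'
#' @param anova An ANOVA tibble from [f_test()], or a named list of them
#'   (one curve per pipeline).
#' @return A ggplot with the highlighted 0.02 and 0.05 cutoffs.
#' @export
plot_fstat_cdf <- function(anova) {
  if (inherits(anova, "data.frame")) anova <- list(pipeline = anova)
  df <- purrr::imap_dfr(anova, function(a, nm)
    dplyr::mutate(fstat_cdf(a), pipeline = nm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$fraction,
                                   colour = .data$pipeline)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = c(0.02, 0.05), linetype = "dotted") +
    ggplot2::labs(x = "FDR-adjusted p-value cutoff", y = "fraction of probes")
}

#' Density plot of the ANOVA mean squares
#'
#' Overlays kernel densities of `msq_between` and `msq_within` with the
#' artificial benchmark between-group mean square as a dashed line.
#'
#' @param anova An ANOVA tibble from [f_test()].
#' @param benchmark_group_means,benchmark_n Benchmark definition, as in
#'   [msq_summaries()].
#' @param xmax Truncate the x axis (default 3 x benchmark).
#' @return A ggplot.
#' @export
plot_msq_densities <- function(anova, benchmark_group_means = c(6, 6, 7),
                               benchmark_n = 4, xmax = NULL) {
  bench <- group_msq(lapply(benchmark_group_means, rep,
                            times = benchmark_n))[["msq_between"]]
  df <- tidyr::pivot_longer(anova[, c("msq_between", "msq_within")],
                            dplyr::everything(),
                            names_to = "statistic", values_to = "msq")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$msq,
                                        colour = .data$statistic)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = bench, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "mean square", y = "density")
  if (!is.null(xmax)) p <- p + ggplot2::coord_cartesian(xlim = c(0, xmax))
  p
}

#' Volcano plot with fitted trend
#'
#' @param modt A moderated-t tibble from [moderated_t()].
#' @param span Trend smoother span.
#' @return A ggplot faceted by comparison.
#' @export
plot_volcano <- function(modt, span = 0.5) {
  vs <- volcano_summary(modt, span = span)
  df <- tidyr::unnest(vs[, c("comparison", "trend")], "trend")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$neglog_p),
                        alpha = 0.3, size = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend), colour = "steelblue") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "log2 ratio", y = "-log10(p)")
}

#' Residual-SD versus intensity trend plot
#'
#' @param object An `sd_trend` from [residual_sd_trend()].
#' @param ... Unused.
#' @return A ggplot with one panel per intensity axis.
#' @export
autoplot.sd_trend <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$by_mean, axis = "mean expression"),
    dplyr::mutate(object$by_min, axis = "minimum expression"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~axis, scales = "free_x") +
    ggplot2::labs(x = "intensity", y = "binned median residual SD")
}
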
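#' Quality score for a fold-change correlation
#'
#' Printed cut-offs of the benchmarking scheme: 2 for r >= 0.96, 1 for
#' r in \[0.94, 0.96), 0 for \[0.92, 0.94), -1 for (0.9, 0.92), and -2 for
#' r <= 0.9.
#'
#' @param r Pearson correlation coefficient(s).
#' @return Integer score(s) in -2..2.
#' @export
correlation_score <- function(r) {
  vapply(r, function(ri) {
    if (ri >= 0.96) 2L
    else if (ri >= 0.94) 1L
    else if (ri >= 0.92) 0L
    else if (ri > 0.90) -1L
    else -2L
  }, integer(1))
}

#' Pearson correlation of pipeline versus reference fold changes
#'
#' Pools all matched (gene, comparison) pairs across comparisons into one
#' Pearson correlation and scores it with [correlation_score()].
#'
#' @param pipeline_fc Tibble from [pipeline_fold_changes()] (columns
#'   `log2_ratio` = reference and `pipeline_log2_ratio`), or a plain
#'   fold-change tibble to be joined with `reference`.
#' @param reference Optional [reference_fold_changes()] tibble to join on
#'   `gene_id` and `comparison` when `pipeline_fc` lacks the reference
#'   column.
#' @return A list: `pearson_r`, `score`, `n`.
#' @export
fc_correlation <- function(pipeline_fc, reference = NULL) {
  df <- tibble::as_tibble(pipeline_fc)
  if (!"pipeline_log2_ratio" %in% names(df)) {
    abort("pipeline_fc needs a pipeline_log2_ratio column",
          class = "beadnorm_validation_error")
  }
  if (!"log2_ratio" %in% names(df)) {
    if (is.null(reference)) {
      abort("no reference fold changes supplied",
            class = "beadnorm_validation_error")
    }
    miss <- dplyr::anti_join(df, reference, by = c("gene_id", "comparison"))
    if (nrow(miss)) {
      abort(paste0("unmatched gene/comparison pair(s): ",
                   paste(unique(miss$gene_id), collapse = ", ")),
            class = "beadnorm_validation_error")
    }
    df <- dplyr::inner_join(df, reference, by = c("gene_id", "comparison"))
  }
  if (nrow(df) < 3) {
    abort("need at least 3 matched (gene, comparison) pairs",
          class = "beadnorm_validation_error")
  }
  r <- cor(df$log2_ratio, df$pipeline_log2_ratio, method = "pearson")
  list(pearson_r = r, score = correlation_score(r), n = nrow(df))
}

#' Bin AUC values into quality scores
#'
#' Sorts the per-pipeline AUC values ascending (ties broken by pipeline
#' name, lexicographic, so the assignment is deterministic) and allocates
#' them to bins of the given sizes, assigned the given scores; the default
#' is bins of 5, 18 and 2 pipelines scoring -1, 0 and +1.
#'
#' @param auc_by_pipeline Named numeric vector of AUC values.
#' @param bin_sizes Integer bin sizes, summing to the number of values.
#' @param bin_scores One score per bin, ascending with the AUC.
#' @return Named integer vector of scores in the input order.
#' @export
auc_bin_scores <- function(auc_by_pipeline, bin_sizes = c(5L, 18L, 2L),
                           bin_scores = c(-1L, 0L, 1L)) {
  if (is.null(names(auc_by_pipeline))) {
    abort("auc_by_pipeline must be named", class = "beadnorm_validation_error")
  }
  if (sum(bin_sizes) != length(auc_by_pipeline) ||
      length(bin_sizes) != length(bin_scores)) {
    abort("bin sizes must sum to the number of AUC values",
          class = "beadnorm_validation_error")
  }
  o <- order(auc_by_pipeline, names(auc_by_pipeline))
  scores <- rep(as.integer(bin_scores), times = bin_sizes)
  out <- integer(length(auc_by_pipeline))
  out[o] <- scores
  setNames(out, names(auc_by_pipeline))
}

#' Bin regression slopes into quality scores
#'
#' Bins each slope by four user-supplied strictly increasing cut points
#' into scores -2..2 (higher slope never scores lower). The cut points make
#' the visually chosen jumps of the original scheme explicit and
#' configurable.
#'
#' @param slopes_by_pipeline Named numeric vector of orthogonal-regression
#'   slopes.
#' @param cut_points Strictly increasing numeric vector of length 4.
#' @return Named integer vector of scores in -2..2.
#' @export
slope_bin_scores <- function(slopes_by_pipeline,
                             cut_points = c(0.55, 0.65, 0.75, 0.9)) {
  if (length(cut_points) != 4 || any(diff(cut_points) <= 0)) {
    abort("cut_points must be 4 strictly increasing values",
          class = "beadnorm_validation_error")
  }
  out <- findInterval(slopes_by_pipeline, cut_points) - 2L
  setNames(as.integer(out), names(slopes_by_pipeline))
}

#' Map a raw measure statistic to a quality score by cut points
#'
#' Generic step-function scorer used for the dispersion-, flatness- and
#' asymmetry-style statistics where lower values are better: four strictly
#' increasing cut points split the range into scores 2, 1, 0, -1, -2 (or
#' the reverse for `lower_is_better = FALSE`).
#'
#' @param value Numeric statistic(s).
#' @param cut_points Strictly increasing numeric vector of length 4.
#' @param lower_is_better Whether small values are good (default `TRUE`).
#' @return Integer score(s) in -2..2.
#' @export
score_by_cuts <- function(value, cut_points, lower_is_better = TRUE) {
  if (length(cut_points) != 4 || any(diff(cut_points) <= 0)) {
    abort("cut_points must be 4 strictly increasing values",
          class = "beadnorm_validation_error")
  }
  idx <- findInterval(value, cut_points)
  out <- if (lower_is_better) 2L - idx else idx - 2L
  as.integer(out)
}

#' Aggregate per-measure scores into the evaluation matrix
#'
#' Builds the pipeline x measure score matrix, its row sums (the quantity
#' the final pipeline choice is based on), a descending ranking by sum
#' (ties broken by name), and hierarchical-clustering orders for rows and
#' columns using Manhattan distance with complete linkage. Missing cells
#' are treated as 0 with a warning; duplicate (pipeline, measure) cells are
#' an error. Manual expert overrides can replace any cell.
#'
#' @param scores Tibble with columns `pipeline`, `measure`, `score`.
#' @param manual_overrides Optional tibble with the same columns whose
#'   values replace computed cells.
#' @return An object of class `eval_matrix`: `scores` (matrix),
#'   `row_sums`, `ranking` (tibble), `row_order`, `col_order`.
#' @export
aggregate_scores <- function(scores, manual_overrides = NULL) {
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("pipeline", "measure", "score") %in% names(scores)))
  if (!is.null(manual_overrides)) {
    manual_overrides <- tibble::as_tibble(manual_overrides)
    scores <- dplyr::rows_update(
      scores, manual_overrides[, c("pipeline", "measure", "score")],
      by = c("pipeline", "measure"), unmatched = "ignore")
  }
  if (anyDuplicated(scores[, c("pipeline", "measure")])) {
    abort("duplicate (pipeline, measure) cell",
          class = "beadnorm_validation_error")
  }
  if (any(abs(scores$score) > 2)) {
    abort("scores must lie in -2..2", class = "beadnorm_validation_error")
  }
  wide <- tidyr::pivot_wider(scores, names_from = "measure",
                             values_from = "score")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$pipeline
  if (anyNA(m)) {
    warn(paste0(sum(is.na(m)), " missing pipeline x measure cell(s) treated as 0"))
    m[is.na(m)] <- 0
  }
  row_sums <- rowSums(m)
  ranking <- tibble::tibble(pipeline = rownames(m), total = row_sums) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$pipeline)
  row_order <- if (nrow(m) > 2) {
    hclust(dist(m, method = "manhattan"), method = "complete")$order
  } else seq_len(nrow(m))
  col_order <- if (ncol(m) > 2) {
    hclust(dist(t(m), method = "manhattan"), method = "complete")$order
  } else seq_len(ncol(m))
  structure(list(scores = m, row_sums = row_sums, ranking = ranking,
                 row_order = row_order, col_order = col_order),
            class = "eval_matrix")
}

#' @export
print.eval_matrix <- function(x, ...) {
  cat("<eval_matrix> ", nrow(x$scores), " pipelines x ", ncol(x$scores),
      " measures\n", sep = "")
  top <- head(x$ranking, 3)
  cat("  top: ", paste0(top$pipeline, " (", top$total, ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
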
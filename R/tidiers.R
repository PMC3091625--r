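#' Tidy an orthogonal regression fit
#'
#' @param x An `ortho_fit` from [orthogonal_regression()].
#' @param ... Unused.
#' @return One row per coefficient with `term` and `estimate`.
#' @export
tidy.ortho_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.ortho_fit
#' @return For `glance()`: a one-row tibble with the orthogonal-distance
#'   objective and the number of points.
#' @export
glance.ortho_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, n = x$n)
}

#' Tidy a pseudo-ROC curve
#'
#' @param x A `roc_curve` from [pseudo_roc()].
#' @param ... Unused.
#' @return The threshold/fpr/tpr sweep as a tibble.
#' @export
tidy.roc_curve <- function(x, ...) x$curve

#' @rdname tidy.roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_tp = length(x$tp_set),
                 n_tn = length(x$tn_set))
}

#' Tidy an evaluation matrix
#'
#' @param x An `eval_matrix` from [aggregate_scores()].
#' @param ... Unused.
#' @return Long tibble with `pipeline`, `measure`, `score`.
#' @export
tidy.eval_matrix <- function(x, ...) {
  tibble::tibble(
    pipeline = rep(rownames(x$scores), times = ncol(x$scores)),
    measure = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.integer(x$scores))
}

#' @rdname tidy.eval_matrix
#' @export
glance.eval_matrix <- function(x, ...) {
  tibble::tibble(n_pipelines = nrow(x$scores), n_measures = ncol(x$scores),
                 best_pipeline = x$ranking$pipeline[1],
                 best_total = x$ranking$total[1])
}
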
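#' Bead-summary expression container
#'
#' A `bead_profile` holds probe-level bead-summary data for one experiment:
#' the per-sample mean bead signal (`avg_signal`, arbitrary fluorescence
#' units), the standard error of that mean across beads (`bead_stderr`), the
#' number of beads contributing to each summary (`n_beads`), and optionally a
#' detection p-value per probe and sample. All components are probe x sample
#' matrices with shared dimnames. Negative intensities are legal: BeadStudio
#' style background subtraction routinely produces them, and positivity is
#' only enforced by the transforms that need it.
#'
#' @param avg_signal Numeric probe x sample matrix of mean bead intensities.
#' @param bead_stderr Optional matrix (same shape) of bead-level standard
#'   errors of the mean; must be non-negative.
#' @param n_beads Optional integer matrix (same shape) of bead counts, >= 1.
#' @param detection_p Optional matrix of detection p-values in \[0, 1\].
#' @param probe_id,sample_id Character vectors of labels; defaults taken from
#'   the dimnames of `avg_signal`.
#'
#' @return An object of class `bead_profile`.
#' @export
bead_profile <- function(avg_signal, bead_stderr = NULL, n_beads = NULL,
                         detection_p = NULL,
                         probe_id = rownames(avg_signal),
                         sample_id = colnames(avg_signal)) {
  avg_signal <- as.matrix(avg_signal)
  if (is.null(probe_id)) {
    probe_id <- sprintf("probe_%d", seq_len(nrow(avg_signal)))
  }
  if (is.null(sample_id)) {
    sample_id <- sprintf("sample_%d", seq_len(ncol(avg_signal)))
  }
  probe_id <- as.character(probe_id)
  sample_id <- as.character(sample_id)
  if (anyDuplicated(probe_id)) {
    abort("probe_id must be unique", class = "beadnorm_validation_error")
  }
  check_shape <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(avg_signal))) {
      abort(paste0(what, " must have the same shape as avg_signal"),
            class = "beadnorm_validation_error")
    }
    dimnames(m) <- list(probe_id, sample_id)
    m
  }
  dimnames(avg_signal) <- list(probe_id, sample_id)
  bead_stderr <- check_shape(bead_stderr, "bead_stderr")
  n_beads <- check_shape(n_beads, "n_beads")
  detection_p <- check_shape(detection_p, "detection_p")
  if (!is.null(bead_stderr) && any(bead_stderr < 0, na.rm = TRUE)) {
    abort("bead_stderr must be >= 0", class = "beadnorm_validation_error")
  }
  if (!is.null(n_beads) && any(n_beads < 1, na.rm = TRUE)) {
    abort("n_beads must be >= 1", class = "beadnorm_validation_error")
  }
  if (!is.null(detection_p) &&
      any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
    abort("detection_p must lie in [0, 1]", class = "beadnorm_validation_error")
  }
  structure(
    list(probe_id = probe_id, sample_id = sample_id,
         avg_signal = avg_signal, bead_stderr = bead_stderr,
         n_beads = n_beads, detection_p = detection_p),
    class = "bead_profile"
  )
}

#' @export
print.bead_profile <- function(x, ...) {
  cat("<bead_profile> ", length(x$probe_id), " probes x ",
      length(x$sample_id), " samples\n", sep = "")
  comps <- c("avg_signal",
             if (!is.null(x$bead_stderr)) "bead_stderr",
             if (!is.null(x$n_beads)) "n_beads",
             if (!is.null(x$detection_p)) "detection_p")
  cat("  components:", paste(comps, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.bead_profile <- function(x) dim(x$avg_signal)

#' @describeIn bead_profile Long-format view: one row per probe x sample.
#' @param x A `bead_profile`.
#' @param ... Unused.
#' @method as_tibble bead_profile
#' @export
as_tibble.bead_profile <- function(x, ...) {
  out <- tibble::tibble(
    probe_id = rep(x$probe_id, times = length(x$sample_id)),
    sample_id = rep(x$sample_id, each = length(x$probe_id)),
    avg_signal = as.vector(x$avg_signal)
  )
  if (!is.null(x$bead_stderr)) out$bead_stderr <- as.vector(x$bead_stderr)
  if (!is.null(x$n_beads)) out$n_beads <- as.vector(x$n_beads)
  if (!is.null(x$detection_p)) out$detection_p <- as.vector(x$detection_p)
  out
}

#' Negative-control profile
#'
#' Mean signals of negative-control beads, one row per control bead type and
#' one column per sample. Used for BeadStudio-style background subtraction
#' and for detection p-values.
#'
#' @param avg_signal Numeric control x sample matrix.
#' @param control_id,sample_id Label vectors; defaults from dimnames.
#' @return An object of class `control_profile`.
#' @export
control_profile <- function(avg_signal,
                            control_id = rownames(avg_signal),
                            sample_id = colnames(avg_signal)) {
  avg_signal <- as.matrix(avg_signal)
  if (is.null(control_id)) control_id <- paste0("neg_", seq_len(nrow(avg_signal)))
  if (is.null(sample_id)) sample_id <- paste0("sample_", seq_len(ncol(avg_signal)))
  if (!all(is.finite(avg_signal))) {
    abort("control signals must be finite", class = "beadnorm_validation_error")
  }
  dimnames(avg_signal) <- list(as.character(control_id), as.character(sample_id))
  structure(list(control_id = as.character(control_id),
                 sample_id = as.character(sample_id),
                 avg_signal = avg_signal),
            class = "control_profile")
}

#' @export
print.control_profile <- function(x, ...) {
  cat("<control_profile> ", length(x$control_id), " controls x ",
      length(x$sample_id), " samples\n", sep = "")
  invisible(x)
}

#' Validate a sample design table
#'
#' The design maps each array to an experimental group (e.g. a time point x
#' treatment combination) and a replicate index. Variance measures need at
#' least two replicates per group; groups with a single sample are kept but
#' flagged with a warning.
#'
#' @param design A data frame with columns `sample_id`, `group`, `replicate`.
#' @param profile_samples Optional character vector of sample ids that must
#'   all appear in the design (e.g. the samples of a profile).
#' @return A tibble with the same columns, validated; extra columns are kept.
#' @export
sample_design <- function(design, profile_samples = NULL) {
  design <- tibble::as_tibble(design)
  needed <- c("sample_id", "group", "replicate")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols)) {
    abort(paste0("design is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "beadnorm_format_error")
  }
  design$sample_id <- as.character(design$sample_id)
  design$group <- as.character(design$group)
  design$replicate <- as.integer(design$replicate)
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup)) {
    abort(paste0("duplicate sample_id in design: ",
                 paste(unique(dup), collapse = ", ")),
          class = "beadnorm_validation_error")
  }
  if (!is.null(profile_samples)) {
    miss <- setdiff(profile_samples, design$sample_id)
    if (length(miss)) {
      abort(paste0("design is missing profiled sample(s): ",
                   paste(miss, collapse = ", ")),
            class = "beadnorm_validation_error")
    }
  }
  n_per <- table(design$group)
  singles <- names(n_per)[n_per < 2]
  if (length(singles)) {
    warn(paste0("group(s) with a single sample (unusable for variance ",
                "measures): ", paste(singles, collapse = ", ")))
    attr(design, "singleton_groups") <- singles
  }
  design
}

#' Reference fold-change table
#'
#' Holds qRT-PCR-style reference log2 ratios: one row per gene and group
#' comparison, the comparison encoded as "<treated>_vs_<control>".
#'
#' @param fc A data frame with columns `gene_id`, `comparison`, `log2_ratio`.
#' @return A validated tibble; extra columns are kept as annotations.
#' @export
reference_fold_changes <- function(fc) {
  fc <- tibble::as_tibble(fc)
  needed <- c("gene_id", "comparison", "log2_ratio")
  missing_cols <- setdiff(needed, names(fc))
  if (length(missing_cols)) {
    abort(paste0("fold-change table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "beadnorm_format_error")
  }
  fc$gene_id <- as.character(fc$gene_id)
  fc$comparison <- as.character(fc$comparison)
  fc$log2_ratio <- as.numeric(fc$log2_ratio)
  if (!all(is.finite(fc$log2_ratio))) {
    abort("log2_ratio must be finite", class = "beadnorm_validation_error")
  }
  fc
}
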
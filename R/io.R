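#' Read a BeadStudio-style Sample Probe Profile
#'
#' Reads the tab-delimited bead-summary export dialect: one header row, lead
#' columns `ProbeID` (and optionally `TargetID`), then per-sample column
#' blocks named `<sample>.AVG_Signal`, `<sample>.BEAD_STDERR`,
#' `<sample>.Avg_NBEADS` and `<sample>.Detection Pval`. Only the
#' `AVG_Signal` block is mandatory; absent blocks yield absent components in
#' the returned [bead_profile()], not errors. Parsing is locale independent
#' (tab delimiter, `.` decimal point).
#'
#' @param path Path to a tab-delimited profile file.
#' @return A [bead_profile()].
#' @export
read_sample_probe_profile <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "beadnorm_io_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        locale = readr::locale(decimal_mark = "."),
                        name_repair = "minimal")
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(paste0("parse error in ", path, " at line ", probs$row[1], ": ",
                 probs$expected[1], " vs ", probs$actual[1]),
          class = "beadnorm_parse_error")
  }
  nms <- names(df)
  id_col <- intersect(c("ProbeID", "TargetID"), nms)
  if (!length(id_col)) {
    abort("malformed header: no ProbeID/TargetID column",
          class = "beadnorm_format_error")
  }
  blocks <- c(avg_signal = "AVG_Signal", bead_stderr = "BEAD_STDERR",
              n_beads = "Avg_NBEADS", detection_p = "Detection Pval")
  rest <- setdiff(nms, c("ProbeID", "TargetID"))
  pat <- paste0("^(.+)\\.(", paste(blocks, collapse = "|"), ")$")
  bad <- rest[!grepl(pat, rest)]
  if (length(bad)) {
    abort(paste0("malformed header: unrecognized column '", bad[1], "'"),
          class = "beadnorm_format_error")
  }
  sample_of <- sub(pat, "\\1", rest)
  block_of <- sub(pat, "\\2", rest)
  samples <- unique(sample_of)
  probe_id <- as.character(df[[id_col[1]]])

  pull_block <- function(block) {
    cols <- paste0(samples, ".", block)
    if (!all(cols %in% rest)) {
      if (any(cols %in% rest)) {
        abort(paste0("malformed header: incomplete '", block, "' block"),
              class = "beadnorm_format_error")
      }
      return(NULL)
    }
    m <- as.matrix(df[cols])
    if (nrow(m) == 0) {
      m <- matrix(numeric(0), 0, length(cols))
    } else if (!is.numeric(m)) {
      abort(paste0("non-numeric values in '", block, "' block"),
            class = "beadnorm_parse_error")
    }
    dimnames(m) <- list(probe_id, samples)
    m
  }
  avg <- pull_block("AVG_Signal")
  if (is.null(avg)) {
    abort("malformed header: no '.AVG_Signal' columns",
          class = "beadnorm_format_error")
  }
  bead_profile(avg,
               bead_stderr = pull_block("BEAD_STDERR"),
               n_beads = pull_block("Avg_NBEADS"),
               detection_p = pull_block("Detection Pval"),
               probe_id = probe_id, sample_id = samples)
}

fmt_num <- function(x, digits = 6L) {
  out <- formatC(x, digits = digits, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

#' Write a Sample Probe Profile
#'
#' Inverse of [read_sample_probe_profile()]. Numeric values are written with
#' 6 significant digits, the declared round-trip precision of the dialect.
#' Components absent from the profile are simply omitted from the file.
#'
#' @param profile A [bead_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_probe_profile <- function(profile, path) {
  stopifnot(inherits(profile, "bead_profile"))
  out <- tibble::tibble(ProbeID = profile$probe_id)
  blocks <- list(AVG_Signal = profile$avg_signal,
                 BEAD_STDERR = profile$bead_stderr,
                 Avg_NBEADS = profile$n_beads,
                 `Detection Pval` = profile$detection_p)
  for (s in profile$sample_id) {
    for (b in names(blocks)) {
      if (is.null(blocks[[b]])) next
      v <- blocks[[b]][, s]
      out[[paste0(s, ".", b)]] <-
        if (b == "Avg_NBEADS") format(as.integer(round(v))) else fmt_num(v)
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a labelled probe x sample matrix
#'
#' Plain matrix TSV: first column `probe_id`, remaining columns one per
#' sample. Probe and sample order is preserved exactly as on disk.
#'
#' @param path File path.
#' @return For the reader, a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "beadnorm_io_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(paste0("parse error in ", path, " at line ", probs$row[1]),
          class = "beadnorm_parse_error")
  }
  if (ncol(df) < 2) {
    abort("matrix TSV needs a probe_id column plus >= 1 sample column",
          class = "beadnorm_format_error")
  }
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) {
    abort(paste0("non-numeric cell in ", path), class = "beadnorm_parse_error")
  }
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_matrix_tsv
#' @param m Numeric matrix with row and column names.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  out <- tibble::as_tibble(as.data.frame(apply(m, 2, fmt_num, simplify = TRUE)),
                           .name_repair = "minimal")
  names(out) <- colnames(m) %||% paste0("sample_", seq_len(ncol(m)))
  out <- dplyr::bind_cols(
    tibble::tibble(probe_id = rownames(m) %||% paste0("probe_", seq_len(nrow(m)))),
    out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' TSV with columns `sample_id`, `group`, `replicate`; extra columns are
#' preserved as annotations.
#'
#' @inheritParams read_matrix_tsv
#' @param profile_samples Optional sample ids that must all be present.
#' @return A validated design tibble (see [sample_design()]).
#' @export
read_design <- function(path, profile_samples = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "beadnorm_io_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sample_design(df, profile_samples = profile_samples)
}

#' @rdname read_design
#' @param design A design tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' Read / write a reference fold-change table
#'
#' TSV with columns `gene_id`, `comparison`, `log2_ratio` holding
#' qRT-PCR-style reference log2 ratios.
#'
#' @inheritParams read_matrix_tsv
#' @return A validated tibble (see [reference_fold_changes()]).
#' @export
read_reference_fold_changes <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "beadnorm_io_error")
  }
  reference_fold_changes(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_reference_fold_changes
#' @param fc A fold-change tibble.
#' @export
write_reference_fold_changes <- function(fc, path) {
  fc$log2_ratio <- fmt_num(fc$log2_ratio)
  readr::write_tsv(fc, path, progress = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping
#'
#' Two-column TSV (`probe_id`, `gene_id`) used to resolve reference
#' fold-change genes to array probes.
#'
#' @inheritParams read_matrix_tsv
#' @return A tibble with columns `probe_id` and `gene_id`.
#' @export
read_probe_gene_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(df))) {
    abort("mapping needs columns probe_id and gene_id",
          class = "beadnorm_format_error")
  }
  tibble::as_tibble(df)
}
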
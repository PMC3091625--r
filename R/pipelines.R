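#' Enumerate the 25 pre-processing pipelines
#'
#' The benchmarked grid combines a background option (`bg` = subtraction of
#' the mean negative-control signal, `noBg` = none), a positivity fix
#' (`forcePos`, `rma`, or none), a transformation (`log`, `vst`, or none),
#' and a between-array normalization (`quantile`, `rsn`, `loess`, `vsn`,
#' `average`, `rankInvariant`, `cubicSpline`, or none). Names follow the
#' grammar `<background>_<transformation>_<normalization>` for R-style
#' pipelines and `<background>_<normalization>` for BeadStudio-style
#' pipelines, which normalize on the original intensity scale and
#' log2-transform afterwards. Positivity fixes only appear together with
#' background subtraction and log transformation; `vst` and `vsn` handle
#' negative values natively and are never combined with a positivity fix.
#'
#' @return A tibble with one row per pipeline: `name`, `background`,
#'   `positivity`, `transform`, `normalization`, `style`.
#' @export
enumerate_pipelines <- function() {
  rows <- list()
  add <- function(name, background, positivity, transform, normalization,
                  style) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = name, background = background, positivity = positivity,
      transform = transform, normalization = normalization, style = style)
  }
  for (bgo in c("bg", "noBg")) {
    pos_noNorm <- if (bgo == "bg") "forcePos" else "none"
    add(paste0(bgo, "_noNorm"), bgo, pos_noNorm, "log", "none", "r")
    for (nm in c("average", "rankInvariant", "cubicSpline")) {
      add(paste0(bgo, "_", nm), bgo, "none", "none", nm, "beadstudio")
    }
    add(paste0(bgo, "_vsn"), bgo, "none", "none", "vsn", "r")
  }
  for (nm in c("loess", "quantile", "rsn")) {
    add(paste0("bg_forcePos_log_", nm), "bg", "forcePos", "log", nm, "r")
    add(paste0("bg_rma_log_", nm), "bg", "rma", "log", nm, "r")
    add(paste0("bg_vst_", nm), "bg", "none", "vst", nm, "r")
    add(paste0("noBg_log_", nm), "noBg", "none", "log", nm, "r")
    add(paste0("noBg_vst_", nm), "noBg", "none", "vst", nm, "r")
  }
  out <- dplyr::bind_rows(rows)
  stopifnot(nrow(out) == 25, !anyDuplicated(out$name))
  out
}

#' Parse a pipeline name into its stage specification
#'
#' Inverse of the naming grammar used by [enumerate_pipelines()]; parsing
#' any enumerated name recovers its row exactly.
#'
#' @param name Pipeline name string, e.g. `"noBg_log_rsn"`.
#' @return A one-row pipeline tibble.
#' @export
parse_pipeline_name <- function(name) {
  grid <- enumerate_pipelines()
  hit <- grid[grid$name == name, ]
  if (nrow(hit) != 1) {
    abort(paste0("unknown pipeline name: '", name, "'; see enumerate_pipelines()"),
          class = "beadnorm_validation_error")
  }
  hit
}

apply_normalization <- function(m, method, options = list()) {
  switch(method,
    none = m,
    quantile = quantile_normalize(m),
    rsn = do.call(rsn_normalize, c(list(m), options$rsn %||% list())),
    loess = do.call(loess_normalize, c(list(m), options$loess %||% list())),
    vsn = do.call(vsn_normalize, c(list(m), options$vsn %||% list())),
    average = average_normalize(m),
    rankInvariant = do.call(rank_invariant_normalize,
                            c(list(m), options$rank_invariant %||% list())),
    cubicSpline = do.call(cubic_spline_normalize,
                          c(list(m), options$cubic_spline %||% list())),
    abort(paste0("unknown normalization: ", method),
          class = "beadnorm_validation_error")
  )
}

#' Run one pre-processing pipeline
#'
#' Applies the stages of a pipeline in order — background, positivity fix,
#' transformation, between-array normalization — and always returns a probe
#' x sample matrix on a log2-like scale. BeadStudio-style pipelines
#' (`average`, `rankInvariant`, `cubicSpline`) normalize on the original
#' intensity scale and are log2-transformed afterwards (with a global
#' positivity shift when background subtraction produced values below 1);
#' `vsn` produces a generalized-log scale directly; `*_noNorm` pipelines
#' skip normalization.
#'
#' @param spec A pipeline name or a one-row tibble from
#'   [enumerate_pipelines()].
#' @param profile A [bead_profile()].
#' @param controls A [control_profile()]; required when the pipeline uses
#'   background subtraction.
#' @param options Named list of per-method options (`rsn`, `loess`, `vsn`,
#'   `rank_invariant`, `cubic_spline`, `vst`).
#' @return A probe x sample matrix on a log2-like scale.
#' @export
run_pipeline <- function(spec, profile, controls = NULL, options = list()) {
  if (is.character(spec)) spec <- parse_pipeline_name(spec)
  stopifnot(inherits(profile, "bead_profile"))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline '", spec$name, "', stage '", name, "': ",
                   conditionMessage(e)),
            class = "beadnorm_pipeline_error")
    })
  }
  work <- profile
  if (spec$background == "bg") {
    if (is.null(controls)) {
      abort(paste0("pipeline '", spec$name, "' needs a negative-control profile"),
            class = "beadnorm_validation_error")
    }
    work <- stage("background", subtract_background(work, controls))
  }
  m <- work$avg_signal

  if (spec$positivity == "forcePos") m <- stage("forcePos", force_positive(m))
  if (spec$positivity == "rma") m <- stage("rma", rma_background(m))

  if (spec$style == "beadstudio") {
    m <- stage(spec$normalization, apply_normalization(m, spec$normalization, options))
    m <- stage("log2", log2_transform(force_positive(m)))
    return(m)
  }

  m <- switch(spec$transform,
    log = stage("log2", log2_transform(m)),
    vst = stage("vst", do.call(vst_transform,
                               c(list(profile, signal = m), options$vst %||% list()))),
    none = m)

  stage(spec$normalization, apply_normalization(m, spec$normalization, options))
}

#' Run many pipelines at once
#'
#' @param profile,controls,options As in [run_pipeline()].
#' @param pipelines Character vector of pipeline names, or `"all"`.
#' @return A named list of log2-scale matrices, one per pipeline.
#' @export
run_pipelines <- function(profile, controls = NULL, pipelines = "all",
                          options = list()) {
  grid <- enumerate_pipelines()
  names_wanted <- if (identical(pipelines, "all")) grid$name else pipelines
  bad <- setdiff(names_wanted, grid$name)
  if (length(bad)) {
    abort(paste0("unknown pipeline name(s): ", paste(bad, collapse = ", ")),
          class = "beadnorm_validation_error")
  }
  out <- lapply(names_wanted, function(nm)
    run_pipeline(nm, profile, controls, options))
  setNames(out, names_wanted)
}
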
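#' Simulation configuration for synthetic bead-array experiments
#'
#' Defines the generative model used by [simulate_experiment()]. The observed
#' mean signal of probe g on array j in group i is
#' \deqn{y_{gij} = b_{gij} + s_{gi} a_j e^{\eta_{gij}}}
#' with additive background `b ~ Normal(bg_mean, bg_sd^2)` truncated at zero,
#' true signal `s_gi = 2^(baseline_g + delta_gi)` (the group effect `delta`
#' is zero for non-deregulated probes), a per-array scale factor `a_j`, and
#' multiplicative log-scale noise `eta ~ Normal(0, mult_cv^2)`. Negative
#' controls carry background only. Bead counts follow a shifted Poisson with
#' the given mean (minimum 1) and the bead-level standard deviation is
#' `sqrt(bg_sd^2 + (mult_cv * signal)^2)`, consistent with the
#' additive-plus-multiplicative error model.
#'
#' The defaults emulate the study design the package benchmarks: three
#' time-point groups in four replicates, an average of 15 beads per probe,
#' a panel of 20 designated true-positive genes, and mild array-to-array
#' scale distortion (log-normal, sdlog 0.1) so that between-array
#' normalization is non-trivial.
#'
#' @param n_probes Number of regular probes.
#' @param n_negative_controls Number of negative-control bead types.
#' @param groups Named integer vector: replicate count per group label.
#' @param de_fraction Proportion of probes truly deregulated.
#' @param effect_size_range Length-2 numeric: range of |true log2 fold
#'   change| for deregulated probes (sign is random per probe, consistent
#'   across groups).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of true log2
#'   expression baselines.
#' @param bg_mean,bg_sd Additive background mean and SD (intensity units).
#' @param mult_cv Multiplicative noise SD on the natural-log scale.
#' @param array_scale_sd sdlog of the log-normal per-array scale factors;
#'   0 disables scale distortion.
#' @param mean_beads Mean bead count per probe and array.
#' @param n_tp_genes Size of the designated true-positive panel.
#' @param reference_noise_sd SD of the measurement noise added to true log2
#'   fold changes when deriving the qRT-PCR-like reference table.
#' @param seed Integer seed; identical seed gives identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_probes = 2000,
                              n_negative_controls = 100,
                              groups = c("2h" = 4L, "4h" = 4L, "12h" = 4L),
                              de_fraction = 0.05,
                              effect_size_range = c(1, 2),
                              baseline_log2_mean = 7.5,
                              baseline_log2_sd = 1.5,
                              bg_mean = 100,
                              bg_sd = 15,
                              mult_cv = 0.15,
                              array_scale_sd = 0.1,
                              mean_beads = 15,
                              n_tp_genes = 20,
                              reference_noise_sd = 0.1,
                              seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_negative_controls = as.integer(n_negative_controls),
              groups = setNames(as.integer(groups), names(groups)),
              de_fraction = de_fraction,
              effect_size_range = as.numeric(effect_size_range),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              bg_mean = bg_mean, bg_sd = bg_sd,
              mult_cv = mult_cv, array_scale_sd = array_scale_sd,
              mean_beads = mean_beads,
              n_tp_genes = as.integer(n_tp_genes),
              reference_noise_sd = reference_noise_sd,
              seed = as.integer(seed))
  if (cfg$n_probes < 1 || cfg$n_negative_controls < 1) {
    abort("n_probes and n_negative_controls must be positive",
          class = "beadnorm_validation_error")
  }
  if (is.null(names(cfg$groups)) || any(!nzchar(names(cfg$groups)))) {
    abort("groups must be a named vector of replicate counts",
          class = "beadnorm_validation_error")
  }
  if (any(cfg$groups < 1)) {
    abort("every group needs at least one replicate",
          class = "beadnorm_validation_error")
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    abort("de_fraction must lie in [0, 1]", class = "beadnorm_validation_error")
  }
  if (cfg$mult_cv < 0 || cfg$bg_sd < 0 || cfg$array_scale_sd < 0) {
    abort("mult_cv, bg_sd and array_scale_sd must be >= 0",
          class = "beadnorm_validation_error")
  }
  if (cfg$mean_beads < 1) {
    abort("mean_beads must be >= 1", class = "beadnorm_validation_error")
  }
  structure(cfg, class = "simulation_config")
}

# Deterministic sub-stream seed per simulation component, kept below 2^31.
stage_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Exact inverse-CDF sampler for Normal(mean, sd) truncated at >= 0.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Simulate a bead-array experiment with known truth
#'
#' Draws a full synthetic experiment from the model described in
#' [simulation_config()]: a [bead_profile()] with bead-summary statistics
#' and detection p-values, a matched [control_profile()], a sample design
#' and a truth set recording which probes are deregulated, their true log2
#' fold changes for every pairwise group comparison, the designated
#' true-positive panel (stratified across baseline-expression terciles) and
#' a noisy qRT-PCR-like reference fold-change table.
#'
#' Detection p-values are defined operationally as the fraction of that
#' sample's negative controls at or above the probe's signal.
#'
#' @param config A [simulation_config()].
#' @return A list of class `bead_sim` with elements `profile`, `controls`,
#'   `design`, `truth` and `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  g_labels <- names(cfg$groups)
  k <- length(g_labels)
  sample_id <- unlist(lapply(g_labels, function(g) {
    paste0(g, "_r", seq_len(cfg$groups[[g]]))
  }))
  group_of <- rep(g_labels, times = cfg$groups)
  n_samples <- length(sample_id)
  n <- cfg$n_probes
  probe_id <- sprintf("probe_%05d", seq_len(n))

  withr_seed <- function(name, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(stage_seed(cfg$seed, name))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code()
  }

  baseline <- withr_seed("baseline", function()
    rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd))

  de_flags <- withr_seed("de", function() {
    flags <- rep(FALSE, n)
    n_de <- round(cfg$de_fraction * n)
    if (n_de > 0) flags[sample.int(n, n_de)] <- TRUE
    flags
  })

  # Per-group effects: baseline group has effect 0; each deregulated probe
  # keeps one direction across groups with independent magnitudes.
  delta <- matrix(0, n, k, dimnames = list(probe_id, g_labels))
  withr_seed("effects", function() {
    idx <- which(de_flags)
    if (length(idx)) {
      sign_g <- sample(c(-1, 1), length(idx), replace = TRUE)
      for (i in seq_len(k)[-1]) {
        mag <- runif(length(idx), cfg$effect_size_range[1],
                     cfg$effect_size_range[2])
        delta[idx, i] <<- sign_g * mag
      }
    }
  })

  a_j <- withr_seed("arrays", function() {
    if (cfg$array_scale_sd == 0) rep(1, n_samples)
    else rlnorm(n_samples, 0, cfg$array_scale_sd)
  })

  s_mat <- 2 ^ (baseline + delta[, group_of, drop = FALSE])
  colnames(s_mat) <- sample_id

  b_mat <- withr_seed("background", function()
    matrix(rtruncnorm0(n * n_samples, cfg$bg_mean, cfg$bg_sd), n, n_samples))
  eta <- withr_seed("noise", function()
    matrix(rnorm(n * n_samples, 0, cfg$mult_cv), n, n_samples))
  signal <- sweep(s_mat, 2, a_j, `*`)
  y <- b_mat + signal * exp(eta)
  dimnames(y) <- list(probe_id, sample_id)

  n_beads <- withr_seed("beads", function()
    matrix(1L + rpois(n * n_samples, max(cfg$mean_beads - 1, 0)),
           n, n_samples))
  bead_sd <- sqrt(cfg$bg_sd^2 + (cfg$mult_cv * signal)^2)
  bead_stderr <- bead_sd / sqrt(n_beads)
  dimnames(n_beads) <- dimnames(bead_stderr) <- dimnames(y)

  ctrl_id <- sprintf("neg_%04d", seq_len(cfg$n_negative_controls))
  ctrl <- withr_seed("controls", function()
    matrix(rtruncnorm0(cfg$n_negative_controls * n_samples,
                       cfg$bg_mean, cfg$bg_sd),
           cfg$n_negative_controls, n_samples,
           dimnames = list(ctrl_id, sample_id)))

  detection_p <- vapply(seq_len(n_samples), function(j) {
    colMeans(outer(ctrl[, j], y[, j], `>=`))
  }, numeric(n))
  dimnames(detection_p) <- dimnames(y)

  profile <- bead_profile(y, bead_stderr = bead_stderr, n_beads = n_beads,
                          detection_p = detection_p,
                          probe_id = probe_id, sample_id = sample_id)
  controls <- control_profile(ctrl, control_id = ctrl_id,
                              sample_id = sample_id)
  design <- sample_design(tibble::tibble(
    sample_id = sample_id, group = group_of,
    replicate = unlist(lapply(cfg$groups, seq_len), use.names = FALSE)))

  comparisons <- utils::combn(k, 2, simplify = FALSE)
  comp_labels <- vapply(comparisons, function(ij)
    paste0(g_labels[ij[2]], "_vs_", g_labels[ij[1]]), character(1))
  true_log2fc <- vapply(comparisons, function(ij)
    delta[, ij[2]] - delta[, ij[1]], numeric(n))
  dimnames(true_log2fc) <- list(probe_id, comp_labels)

  tp_genes <- withr_seed("tp", function() {
    de_idx <- which(de_flags)
    n_tp <- min(cfg$n_tp_genes, length(de_idx))
    if (n_tp == 0) return(character(0))
    terciles <- cut(rank(baseline[de_idx], ties.method = "first"),
                    breaks = 3, labels = FALSE)
    picked <- integer(0)
    for (t in 1:3) {
      pool <- de_idx[terciles == t]
      want <- round(n_tp * sum(terciles == t) / length(de_idx))
      picked <- c(picked, sample(pool, min(want, length(pool))))
    }
    short <- n_tp - length(picked)
    if (short > 0) {
      pool <- setdiff(de_idx, picked)
      picked <- c(picked, sample(pool, min(short, length(pool))))
    }
    probe_id[sort(utils::head(picked, n_tp))]
  })

  truth <- structure(
    list(de_flags = setNames(de_flags, probe_id),
         true_log2fc = true_log2fc,
         tp_genes = tp_genes,
         baseline_log2 = setNames(baseline, probe_id),
         group_effects = delta,
         array_scale_factors = setNames(a_j, sample_id)),
    class = "truth_set")
  truth$reference_fc <- simulate_reference_fold_changes(
    truth, noise_sd = cfg$reference_noise_sd,
    seed = stage_seed(cfg$seed, "reference"))

  structure(list(profile = profile, controls = controls, design = design,
                 truth = truth, config = cfg),
            class = "bead_sim")
}

#' @export
print.bead_sim <- function(x, ...) {
  cat("<bead_sim> ", x$config$n_probes, " probes, ",
      length(x$profile$sample_id), " samples (",
      paste(names(x$config$groups), collapse = "/"), "), ",
      sum(x$truth$de_flags), " deregulated, ",
      length(x$truth$tp_genes), " TP panel genes\n", sep = "")
  invisible(x)
}

#' Derive a qRT-PCR-like reference fold-change table from simulation truth
#'
#' For every designated true-positive gene and every pairwise group
#' comparison the reference log2 ratio is the true log2 fold change plus
#' independent Normal(0, noise_sd^2) measurement noise, mimicking relative
#' quantification of transcript abundance by an independent assay. With
#' `noise_sd = 0` the reference equals the truth exactly.
#'
#' @param truth A `truth_set` from [simulate_experiment()].
#' @param noise_sd Non-negative measurement noise SD (log2 units).
#' @param seed Integer seed.
#' @return A [reference_fold_changes()] tibble with one row per
#'   (gene, comparison) pair.
#' @export
simulate_reference_fold_changes <- function(truth, noise_sd = 0.1,
                                            seed = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  if (noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "beadnorm_validation_error")
  }
  genes <- truth$tp_genes
  comps <- colnames(truth$true_log2fc)
  grid <- tidyr::expand_grid(gene_id = genes, comparison = comps)
  true_vals <- truth$true_log2fc[cbind(grid$gene_id, grid$comparison)]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  noise <- rnorm(nrow(grid), 0, noise_sd)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  reference_fold_changes(
    tibble::tibble(gene_id = grid$gene_id, comparison = grid$comparison,
                   log2_ratio = true_vals + noise))
}
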
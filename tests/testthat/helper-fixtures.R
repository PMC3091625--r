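# Small in-code fixtures shared across test files.

tiny_profile <- function() {
  bead_profile(
    avg_signal = matrix(c(100, 20, 250, 35), 2, 2,
                        dimnames = list(c("p1", "p2"), c("s1", "s2"))),
    bead_stderr = matrix(c(4, 2, 6, 3), 2, 2),
    n_beads = matrix(c(15L, 12L, 18L, 14L), 2, 2),
    detection_p = matrix(c(0, 0.4, 0.01, 0.3), 2, 2))
}

tiny_design <- function() {
  sample_design(tibble::tibble(
    sample_id = c("g1_r1", "g1_r2", "g1_r3", "g1_r4",
                  "g2_r1", "g2_r2", "g2_r3", "g2_r4",
                  "g3_r1", "g3_r2", "g3_r3", "g3_r4"),
    group = rep(c("g1", "g2", "g3"), each = 4),
    replicate = rep(1:4, 3)))
}

# memoized mid-size simulation shared by several test files
.sim_cache <- new.env(parent = emptyenv())
shared_sim <- function(key = "default", ...) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_experiment(simulation_config(...))
  }
  .sim_cache[[key]]
}

# brute-force double-loop ANOVA decomposition, the independent oracle for
# group_msq / f_test
brute_msq <- function(values_by_group) {
  k <- length(values_by_group)
  all_vals <- unlist(values_by_group)
  grand <- mean(all_vals)
  ssb <- 0
  ssw <- 0
  for (i in seq_len(k)) {
    v <- values_by_group[[i]]
    gm <- mean(v)
    ssb <- ssb + length(v) * (gm - grand)^2
    for (x in v) ssw <- ssw + (x - gm)^2
  }
  c(msq_between = ssb / (k - 1),
    msq_within = ssw / (length(all_vals) - k))
}
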
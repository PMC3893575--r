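# Shared fixtures. Scaled exploration runs are expensive, so they are
# computed lazily and memoised for the whole test session.

# Stochastic end-to-end checks may fail in clusters; always run the full
# suite rather than terminating at the default failure cap.
options(testthat.progress.max_fails = 100)

run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = run_cache))
    assign(key, force(expr), envir = run_cache)
  get(key, envir = run_cache)
}

# Reference scaled self-exploration runs: 9 seeds x 60,000 vocalizations
# under the default configuration (the desk-scale study conditions).
scaled_sagg_run <- function(seed) {
  cached(paste0("sagg_", seed), run_sagg_riac(60000, vd_config(), seed = seed))
}

scaled_sagg_seeds <- function() 1:9

# Scaled strategic (emulation) runs: 30,000 vocalizations. All teachers are
# presented to the same learner (common seed), mirroring "the same
# experiment with different acoustic environments".
scaled_sgim_run <- function(teacher_id) {
  cached(paste0("sgim_", teacher_id),
         run_sgim_acts(30000, teacher(teacher_id), vd_config(), seed = 1))
}

# Segmentation of a run under the reference analysis settings.
reference_segmentation <- function(run) {
  p <- windowed_class_proportions(run)
  segment_stages(p)
}

# Stage labels in developmental order.
canonical_sequence <- c("no_phonation_unarticulated", "unarticulated",
                        "articulated")

# A tiny deterministic mixture for conditioning/sampling tests.
toy_mixture_2d <- function() {
  S1 <- matrix(c(1, 0.6, 0.6, 1), 2)
  S2 <- matrix(c(0.5, -0.2, -0.2, 0.8), 2)
  vd_gmm(c(0.4, 0.6), rbind(c(-2, -1), c(3, 2)),
         array(c(S1, S2), c(2, 2, 2)))
}
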
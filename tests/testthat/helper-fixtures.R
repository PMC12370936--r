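# Small image side for unit tests of the network machinery; large enough for
# the layer geometry (the pooled map must admit the 6-wide window).
TEST_SIDE <- 32L

# Expensive shared cohorts (trained agents, reversal runs) are built once per
# test run and memoized here so several test blocks can reuse them.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A rendered pair at the unit-test side.
tiny_pair <- function(alpha = 0.5, predictive = "size", seed = 1) {
  cfg <- task_config(predictive, alpha = alpha, image_side = TEST_SIDE,
                     seed = seed)
  set.seed(seed)
  sample_pair(cfg)
}

# Minimal hand-built trajectory for classifier tests: only the fields that
# classify_pathway() consumes.
fake_trajectory <- function(theta_before, theta_after, dz_before, dz_after,
                            flagged = FALSE) {
  structure(
    list(checkpoints = data.frame(
           phase = c(1L, 2L), pairs_seen = c(160, 320),
           theta = c(theta_before, theta_after),
           mean_dz = c(NA_real_, dz_after),
           accuracy = c(1, 1), train_loss = c(0, 0)),
         phase_alphas = c(0.5, -0.5),
         phase_boundaries = 160,
         final_rule_ref = list(theta = theta_before, mean_dz = dz_before,
                               accuracy = 0),
         flagged = flagged),
    class = "pathway_trajectory")
}
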
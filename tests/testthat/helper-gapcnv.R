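# Shared fixtures, built once per run.

# Small estimator for unit tests of the posterior machinery (the acceptance
# suite trains its own full-budget estimator).
.test_cache <- new.env(parent = emptyenv())

small_estimator <- function() {
  if (is.null(.test_cache$est)) {
    ts <- build_training_set(n_sims = 2000, seed = 2001L)
    .test_cache$est <- train_density_estimator(ts, seed = 2002L)
  }
  .test_cache$est
}

# deterministic strong-signal observation (noiseless trajectory at
# s_C = 0.15, delta_C = 1e-4, phi = 1e-4)
strong_signal_observation <- function() {
  p <- evolution_params(s_C = 0.15, delta_C = 1e-4, phi = 1e-4)
  traj <- simulate_trajectory(p, mode = "deterministic")
  traj$prop_reported[match(p$schedule, traj$generation)]
}

# 1-D Gaussian posterior as a log-density function over point matrices
gaussian_logpdf <- function(mean, sd) {
  function(pts) dnorm(pts[, 1], mean, sd, log = TRUE)
}

flat_logpdf <- function(lo, hi) {
  function(pts) ifelse(pts[, 1] >= lo & pts[, 1] <= hi,
                       -log(hi - lo), -Inf)
}
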
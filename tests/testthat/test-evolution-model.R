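test_that("initial state places all mass on A and C-", {
  expect_equal(init_state(0),
               c(x_A = 1, x_B = 0, x_Cplus = 0, x_Cminus = 0))
  expect_equal(init_state(1e-4),
               c(x_A = 0.9999, x_B = 0, x_Cplus = 0, x_Cminus = 1e-4))
  expect_equal(unname(init_state(1)["x_Cminus"]), 1)
  expect_error(init_state(-0.1))
  expect_error(init_state(1.5))
})

test_that("selection stage matches the normalized fitness update", {
  p0 <- evolution_params(s_C = 0, delta_C = 0, s_B = 0, delta_B = 0)
  st <- c(x_A = 0.7, x_B = 0.1, x_Cplus = 0.15, x_Cminus = 0.05)
  expect_equal(step_selection(st, p0), st)  # neutral

  p <- evolution_params(s_C = 0.1, delta_C = 0)
  st <- c(x_A = 0.9, x_B = 0, x_Cplus = 0.1, x_Cminus = 0)
  out <- step_selection(st, p)
  expect_equal(unname(out["x_Cplus"]), 0.11 / 1.01, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)

  # C+ and C- share a fitness, so equal frequencies stay equal
  st <- c(x_A = 0.9, x_B = 0, x_Cplus = 0.05, x_Cminus = 0.05)
  out <- step_selection(st, evolution_params(s_C = 0.37, delta_C = 0))
  expect_equal(unname(out["x_Cplus"]), unname(out["x_Cminus"]))
})

test_that("mutation stage moves mass only out of the ancestor", {
  p <- evolution_params(s_C = 0.1, delta_C = 1e-4, delta_B = 1e-5)
  out <- step_mutation(init_state(0), p)
  expect_equal(unname(out["x_A"]), 1 - 1e-4 - 1e-5)
  expect_equal(unname(out["x_Cplus"]), 1e-4)
  expect_equal(unname(out["x_B"]), 1e-5)
  expect_equal(sum(out), 1, tolerance = 1e-12)

  p0 <- evolution_params(s_C = 0.1, delta_C = 0, delta_B = 0)
  st <- c(x_A = 0.5, x_B = 0.1, x_Cplus = 0.2, x_Cminus = 0.2)
  expect_equal(step_mutation(st, p0), st)

  # no source genotype, nothing to mutate
  st <- c(x_A = 0, x_B = 0.3, x_Cplus = 0.4, x_Cminus = 0.3)
  expect_equal(step_mutation(st, p), st)
})

test_that("drift is multinomial resampling with the right moments", {
  st <- c(x_A = 1, x_B = 0, x_Cplus = 0, x_Cminus = 0)
  expect_equal(step_drift(st, 100), st)   # degenerate multinomial
  set.seed(42)
  st <- c(x_A = 0.9, x_B = 0, x_Cplus = 0.1, x_Cminus = 0)
  for (i in 1:10) {
    out <- step_drift(st, 1000)
    expect_equal(unname(out[c("x_B", "x_Cminus")]), c(0, 0))  # no resurrection
  }
  # binomial-variance oracle at p = 0.1, N = 1e5
  draws <- replicate(1e4, step_drift(st, 1e5)["x_Cplus"])
  expect_equal(var(draws), 0.1 * 0.9 / 1e5, tolerance = 0.1)
  # deterministic mode disables drift
  expect_equal(step_drift(st, 10, deterministic = TRUE), st)
})

test_that("trajectories follow the logistic closed form without mutation or drift", {
  p <- evolution_params(s_C = 0.15, delta_C = 0, s_B = 0, delta_B = 0,
                        phi = 1e-4, horizon = 137)
  traj <- simulate_trajectory(p, mode = "deterministic")
  expect_equal(traj$prop_total,
               logistic_total(0:137, 0.15, 1e-4), tolerance = 1e-9)
  # continuous-time approximation: ~0.997 total by generation 100
  expect_equal(logistic_total(100, 0.15, 1e-4, discrete = FALSE),
               0.997, tolerance = 0.001)
  expect_true(all(diff(traj$prop_total) >= 0))  # monotone under pure selection
})

test_that("nothing amplifies when there is no CNV supply", {
  p <- evolution_params(s_C = 0.2, delta_C = 0, delta_B = 0, phi = 0,
                        N = 1e6, horizon = 60)
  traj <- simulate_trajectory(p)
  expect_true(all(traj$prop_reported == 0))
  expect_true(all(traj$prop_total == 0))
})

test_that("frequencies stay normalized and reported never exceeds total", {
  set.seed(7)
  for (i in 1:5) {
    p <- evolution_params(s_C = runif(1, 0, 0.3), delta_C = 10^runif(1, -6, -3),
                          phi = 10^runif(1, -6, -3), N = 1e6, horizon = 80)
    traj <- simulate_trajectory(p, keep_states = TRUE)
    sums <- traj$x_A + traj$x_B + traj$x_Cplus + traj$x_Cminus
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(traj$prop_total >= traj$prop_reported))
  }
})

test_that("a lower formation rate widens the reported/total gap", {
  gap_at <- function(delta_C) {
    p <- evolution_params(s_C = 0.15, delta_C = delta_C, phi = 1e-4)
    traj <- simulate_trajectory(p, mode = "deterministic")
    with(traj[traj$generation == 137, ], prop_total - prop_reported)
  }
  expect_gt(gap_at(1e-7), gap_at(1e-4))
})

test_that("stochastic trajectories at N = 1e8 track the deterministic limit", {
  det <- sim_reported_batch(0.15, 1e-4, 1e-4, stochastic = FALSE)
  set.seed(11)
  sto <- sim_reported_batch(rep(0.15, 20), rep(1e-4, 20), rep(1e-4, 20))
  # compare wherever the deterministic proportion is above 1e3/N
  keep <- det$total[1, ] > 1e3 / 1e8
  dev <- abs(sweep(sto$total[, keep, drop = FALSE], 2, det$total[1, keep]))
  expect_lt(max(dev), 0.01)
})
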
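test_that("prior draws are uniform on the documented support", {
  set.seed(101)
  th <- sample_prior(1e5)
  sup <- prior_support()
  for (j in 1:3) {
    expect_true(all(th[[j]] >= sup$lower[j] & th[[j]] <= sup$upper[j]))
  }
  expect_equal(mean(th$log10_sC), -1.0, tolerance = 0.01)
  expect_equal(mean(th$log10_dC), -3.65, tolerance = 0.02)
})

test_that("training sets are reproducible and bookkeeping is exact", {
  a <- build_training_set(n_sims = 1000, seed = 7L)
  b <- build_training_set(n_sims = 1000, seed = 7L)
  expect_identical(a$theta, b$theta)
  expect_identical(a$x, b$x)
  expect_equal(nrow(a$theta), 1000)
  expect_equal(nrow(a$x), 1000)
  expect_equal(ncol(a$x), length(default_schedule()))
})

test_that("amortized posteriors are well-posed over the prior support", {
  est <- small_estimator()
  set.seed(55)
  held_out <- build_training_set(n_sims = 1000, seed = 56L)
  for (i in 1:10) {
    post <- individual_posterior(est, held_out$x[i, ])
    lp <- posterior_logpdf(post, as.matrix(sample_prior(1000)))
    expect_true(all(is.finite(lp)))
  }
  post <- individual_posterior(est, strong_signal_observation())
  s <- as.matrix(posterior_sample(post, 1e4))
  sup <- prior_support()
  for (j in 1:3)
    expect_true(all(s[, j] >= sup$lower[j] & s[, j] <= sup$upper[j]))
  # outside the support the density vanishes
  expect_identical(posterior_logpdf(post, c(0.5, -4, -4)), -Inf)
  expect_error(individual_posterior(est, c(0.1, 0.2)))  # length mismatch
})

test_that("posterior mass integrates to one over the support", {
  est <- small_estimator()
  post <- individual_posterior(est, strong_signal_observation())
  res <- 100  # the collective module's default grid
  axes <- purrr::map2(prior_support()$lower, prior_support()$upper,
                      function(lo, hi) lo + (hi - lo) / res * (1:res - 0.5))
  grid <- as.matrix(expand.grid(axes))
  cell <- prod(purrr::map_dbl(axes, function(a) a[2] - a[1]))
  mass <- sum(exp(posterior_logpdf(post, grid))) * cell
  expect_equal(mass, 1, tolerance = 0.02)
})

test_that("strong-signal observations are recovered sharply", {
  est <- small_estimator()
  truth <- c(log10(0.15), -4, -4)
  post <- individual_posterior(est, strong_signal_observation())
  set.seed(66)
  s <- posterior_sample(post, 1e4)
  expect_lt(abs(median(s$log10_sC) - truth[1]), 0.3)
  map <- map_estimate(post, n_draws = 5000)
  expect_lt(abs(map$log10_sC - truth[1]), 0.3)
  # the MAP is at least as dense as random posterior points
  lp100 <- posterior_logpdf(post, as.matrix(dplyr::slice_sample(s, n = 100)))
  expect_true(all(map$log_density >= lp100))
  # 95% HDIs narrower than one order of magnitude for s_C and delta_C
  h <- marginal_hdi(s[, c("log10_sC", "log10_dC")], 0.95)
  expect_true(all(h$upper - h$lower < 1))
})

test_that("shortest-interval HDI matches known distributions", {
  set.seed(9)
  x <- rnorm(1e5)
  h <- marginal_hdi(cbind(z = x), 0.95)
  expect_equal(h$lower, -1.96, tolerance = 0.05)
  expect_equal(h$upper, 1.96, tolerance = 0.05)
  u <- marginal_hdi(cbind(u = runif(1e5)), 0.95)
  expect_equal(u$upper - u$lower, 0.95, tolerance = 0.01)
  pm <- marginal_hdi(cbind(c = rep(1.5, 200)), 0.95)
  expect_equal(pm$upper - pm$lower, 0)
  expect_error(marginal_hdi(cbind(x), mass = 1.2))
  # shrinking samples toward their mean shrinks the interval accordingly
  h10 <- marginal_hdi(cbind(z = x / 10), 0.95)
  expect_lt(h10$upper - h10$lower, (h$upper - h$lower) / 8)
})

test_that("coverage rejects empty input and reports all coordinates", {
  est <- small_estimator()
  tiny <- build_training_set(n_sims = 1000, seed = 77L)
  tiny$theta <- tiny$theta[1:20, ]
  tiny$x <- tiny$x[1:20, , drop = FALSE]
  set.seed(78)
  cv <- coverage(est, tiny, n_samples = 400)
  expect_equal(cv$parameter, c("log10_sC", "log10_dC", "log10_phi", "joint"))
  expect_true(all(cv$coverage >= 0 & cv$coverage <= 1))
  empty <- tiny
  empty$theta <- empty$theta[0, ]
  empty$x <- empty$x[0, , drop = FALSE]
  expect_error(coverage(est, empty))
})
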
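test_that("Shannon diversity is the effective number of lineages", {
  expect_equal(shannon_diversity(rep(0.25, 4)), 4)
  expect_equal(shannon_diversity(c(1)), 1)
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)), exp(1.5 * log(2)),
               tolerance = 1e-12)
  # invariant to permutation and to scale; bounded by richness
  v <- c(5, 1, 0, 3, 2)
  expect_equal(shannon_diversity(v), shannon_diversity(rev(v)))
  expect_equal(shannon_diversity(v), shannon_diversity(v / sum(v)))
  expect_lte(shannon_diversity(v), sum(v > 0))
  expect_error(shannon_diversity(c(0, 0)))
  expect_error(shannon_diversity(c(-1, 2)))
})

test_that("without formation there is exactly one CNV lineage", {
  p <- evolution_params(s_C = 0.15, delta_C = 0, phi = 1e-4, N = 1e6,
                        horizon = 50)
  set.seed(3)
  lin <- simulate_lineages(p, growth = "stochastic")
  expect_equal(lin$founded_total, 1)
  expect_true(all(lin$generations$diversity[lin$generations$cnv_total > 0] == 1))
})

test_that("lineage founding matches the Poisson rate bookkeeping", {
  p <- evolution_params(s_C = 0.15, delta_C = 1e-4, phi = 1e-5, N = 1e6,
                        horizon = 100)
  set.seed(8)
  lin <- simulate_lineages(p, growth = "stochastic")
  # expected foundings from the realized ancestor frequencies
  lambda <- sum(p$delta_C * head(lin$generations$x_A, -1) * p$N) + 1
  expect_lt(abs(lin$founded_total - lambda), 3 * sqrt(lambda))
})

test_that("lineage frequencies sum to the collapsed model's CNV proportion", {
  p <- evolution_params(s_C = 0.1, delta_C = 1e-3, phi = 1e-3, N = 1e4,
                        horizon = 50)
  det <- sim_reported_batch(p$s_C, p$delta_C, p$phi, p$s_B, p$delta_B,
                            N = p$N, horizon = 50, schedule = 50,
                            stochastic = FALSE)
  set.seed(12)
  finals <- replicate(50, {
    lin <- simulate_lineages(p, growth = "stochastic")
    tail(lin$generations$cnv_total, 1)
  })
  expect_lt(abs(mean(finals) - det$total[1, 1]), 0.02)
  # per-generation totals are valid frequencies
  lin <- simulate_lineages(p, growth = "stochastic")
  expect_true(all(lin$generations$cnv_total >= 0 &
                    lin$generations$cnv_total <= 1))
})

test_that("diversity trajectories rise and then stabilize", {
  p <- strain_presets()$WT
  set.seed(21)
  div <- diversity_trajectory(p, n_reps = 2)
  expect_equal(div$diversity[1], 1)  # the single phi lineage at generation 0
  # nondecreasing through the selection phase in deterministic-growth mode
  rise <- div$diversity[div$generation <= 60]
  expect_true(all(diff(rise) >= -1e-9))
  # stabilized by the equilibrium phase: < 2% change over the last 20 gens
  last <- tail(div$diversity, 20)
  expect_lt(diff(range(last)) / mean(last), 0.02)
})

test_that("posterior-predictive bands behave like the underlying draws", {
  map_draw <- tibble::tibble(log10_sC = log10(0.182),
                             log10_dC = log10(4.5e-5), log10_phi = -5)
  det <- posterior_predictive(map_draw, mode = "deterministic")
  expect_equal(det$reported_q25, det$reported_q75)  # single curve
  expect_true(all(det$total_mean >= det$reported_mean))
  set.seed(31)
  wide <- posterior_predictive(sample_prior(100))
  tight <- posterior_predictive(map_draw[rep(1, 100), ])
  width <- function(x) mean(x$reported_q75 - x$reported_q25)
  expect_gt(width(wide), width(tight))
  expect_error(posterior_predictive(tibble::tibble(
    log10_sC = 1, log10_dC = -4, log10_phi = -4)))
})

test_that("competitions between identical strains are symmetric", {
  p <- strain_presets()$WT
  set.seed(41)
  cmp <- simulate_competition(p, p, n_reps = 1000)
  sem <- sd(cmp$finals) / sqrt(length(cmp$finals))
  expect_lt(abs(cmp$mean_final - 0.5), 3 * sem + 1e-4)
  # frequencies are conserved
  expect_equal(cmp$trajectory$strain_a + cmp$trajectory$strain_b,
               rep(1, nrow(cmp$trajectory)), tolerance = 1e-9)
})

test_that("deterministic competition follows the geometric-growth closed form", {
  # pure fitness contest: all cells are C-, no mutation
  a <- evolution_params(s_C = 0.2, delta_C = 0, s_B = 0, delta_B = 0,
                        phi = 1, N = 1e8, horizon = 10)
  b <- evolution_params(s_C = 0.1, delta_C = 0, s_B = 0, delta_B = 0,
                        phi = 1, N = 1e8, horizon = 10)
  cmp <- simulate_competition(a, b, horizon = 10, mode = "deterministic")
  r <- (1.2 / 1.1)^10
  expect_equal(cmp$mean_final, r / (1 + r), tolerance = 1e-9)
})

test_that("raising a strain's rates never hurts it in competition", {
  set.seed(51)
  base <- evolution_params(s_C = 0.15, delta_C = 1e-5, phi = 1e-5,
                           horizon = 80)
  mean_final <- function(s_C, delta_C) {
    a <- evolution_params(s_C = s_C, delta_C = delta_C, phi = 1e-5,
                          horizon = 80)
    simulate_competition(a, base, horizon = 80, n_reps = 200)$mean_final
  }
  along_s <- purrr::map_dbl(c(0.15, 0.18, 0.21), mean_final, delta_C = 1e-5)
  along_d <- purrr::map_dbl(c(1e-5, 5e-5, 2e-4), mean_final, s_C = 0.15)
  expect_true(all(diff(along_s) >= -0.02))
  expect_true(all(diff(along_d) >= -0.02))
})
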
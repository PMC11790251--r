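#' Posterior-predictive CNV trajectories
#'
#' Simulate one trajectory per parameter draw (times `n_reps`) and summarize
#' the reported and total CNV proportion at each scheduled generation by the
#' median and interquartile band.
#'
#' @param draws Data frame of parameter draws with columns `log10_sC`,
#'   `log10_dC`, `log10_phi` (e.g. from [posterior_sample()]).
#' @param n_reps Stochastic replicates per draw.
#' @param schedule Generations at which to record the prediction.
#' @param N,horizon,s_B,delta_B Model settings shared by all draws.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return Tibble with per-generation quantiles (`q25`, `median`, `q75`) and
#'   means of the reported and total CNV proportion.
#' @export
posterior_predictive <- function(draws, n_reps = 1,
                                 schedule = default_schedule(),
                                 N = 1e8, horizon = 137,
                                 s_B = 1e-3, delta_B = 1e-5,
                                 mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  draws <- as_theta_matrix(draws)
  if (any(!in_box(draws))) abort("draws must lie within the prior support")
  idx <- rep(seq_len(nrow(draws)), each = n_reps)
  sim <- sim_reported_batch(
    10^draws[idx, 1], 10^draws[idx, 2], 10^draws[idx, 3],
    s_B = s_B, delta_B = delta_B, N = N, horizon = horizon,
    schedule = schedule, stochastic = mode == "stochastic")
  qs <- function(m, p) apply(m, 2, quantile, probs = p, names = FALSE)
  tibble(
    generation = schedule,
    reported_q25 = qs(sim$reported, 0.25),
    reported_median = qs(sim$reported, 0.5),
    reported_q75 = qs(sim$reported, 0.75),
    reported_mean = colMeans(sim$reported),
    total_q25 = qs(sim$total, 0.25),
    total_median = qs(sim$total, 0.5),
    total_q75 = qs(sim$total, 0.75),
    total_mean = colMeans(sim$total)
  )
}

#' Lineage-tracked CNV simulation
#'
#' Tracks individual CNV lineages through the Wright-Fisher dynamics: each
#' generation, `Poisson(delta_C * x_A * N)` new CNV lineages are founded (one
#' cell each), all CNV lineages share fitness `1 + s_C`, and the pre-existing
#' unreported class (phi) founds a single lineage at generation 0.
#'
#' Two growth modes are provided. With `growth = "deterministic"` lineages
#' grow at their expected rate (no drift among lineages); cohorts founded in
#' the same generation then stay identical, which keeps the computation
#' compact. With `growth = "stochastic"` every lineage is resampled each
#' generation in one multinomial draw together with the A and B classes.
#' Founding can likewise be `"poisson"` (default) or `"expected"`.
#'
#' @param params A [evolution_params()] object.
#' @param founding `"poisson"` or `"expected"` number of new lineages per
#'   generation.
#' @param growth `"deterministic"` (drift-free lineage growth) or
#'   `"stochastic"` (multinomial drift at single-cell resolution).
#' @param max_lineages Guard: abort if the expected number of founded
#'   lineages exceeds this cap.
#' @param include_phi Count the pre-existing (phi) lineage in the diversity
#'   statistic (default `TRUE`); set to `FALSE` to restrict the effective
#'   number to de novo lineages founded after generation 0.
#' @return A `cnv_lineages` object: `generations` (tibble with per-generation
#'   ancestor/B/CNV frequencies, live lineage count and Shannon diversity)
#'   and `lineages` (tibble of founding generation and final size per
#'   surviving lineage).
#' @export
simulate_lineages <- function(params,
                              founding = c("poisson", "expected"),
                              growth = c("deterministic", "stochastic"),
                              max_lineages = 2e6, include_phi = TRUE) {
  founding <- match.arg(founding)
  growth <- match.arg(growth)
  stopifnot(inherits(params, "cnv_params"))
  if (params$delta_C * params$N * params$horizon > max_lineages)
    abort("expected lineage count exceeds `max_lineages`")
  if (growth == "deterministic") {
    lineages_cohort(params, founding, include_phi)
  } else {
    lineages_multinomial(params, founding, include_phi)
  }
}

# cohort-compressed engine: no drift among lineages; cohort g holds n_g
# lineages of identical size v_g (cells)
lineages_cohort <- function(params, founding, include_phi = TRUE) {
  N <- params$N
  nA <- (1 - params$phi) * N; nB <- 0
  co_n <- if (params$phi > 0) 1 else numeric(0)   # lineages per cohort
  co_v <- if (params$phi > 0) params$phi * N else numeric(0)  # size per lineage
  co_gen <- if (params$phi > 0) 0 else numeric(0)
  founded <- sum(co_n)
  gens <- vector("list", params$horizon + 1)
  gens[[1]] <- cohort_row(0, nA, nB, co_n, co_v, N, include_phi, co_gen)
  for (g in seq_len(params$horizon)) {
    wbar <- (nA + nB * (1 + params$s_B) + sum(co_n * co_v) * (1 + params$s_C)) / N
    nA <- nA / wbar
    nB <- nB * (1 + params$s_B) / wbar
    co_v <- co_v * (1 + params$s_C) / wbar
    lambda <- params$delta_C * (nA / N) * N
    n_new <- if (founding == "poisson") rpois(1, lambda) else lambda
    nB <- nB + params$delta_B * nA
    nA <- nA * (1 - params$delta_C - params$delta_B)
    if (n_new > 0) {
      co_n <- c(co_n, n_new); co_v <- c(co_v, 1); co_gen <- c(co_gen, g)
      founded <- founded + n_new
    }
    gens[[g + 1]] <- cohort_row(g, nA, nB, co_n, co_v, N, include_phi, co_gen)
  }
  lineages <- tibble(founded_gen = co_gen, n_lineages = co_n,
                     final_size = co_v, final_freq = co_v / params$N)
  structure(
    list(generations = dplyr::bind_rows(gens), lineages = lineages,
         founded_total = founded, params = params,
         founding = founding, growth = "deterministic"),
    class = "cnv_lineages"
  )
}

cohort_row <- function(g, nA, nB, co_n, co_v, N, include_phi, co_gen) {
  keep <- if (include_phi) rep(TRUE, length(co_n)) else co_gen > 0
  tibble(
    generation = g,
    x_A = nA / N, x_B = nB / N,
    cnv_total = sum(co_n * co_v) / N,
    n_lineages = sum(co_n[co_v > 0]),
    diversity = if (sum(co_n[keep] * co_v[keep]) > 0)
      shannon_weighted(co_n[keep], co_v[keep]) else NA_real_
  )
}

# effective number of lineages for cohorts (n_i lineages of size v_i each)
shannon_weighted <- function(n, v) {
  keep <- n > 0 & v > 0
  n <- n[keep]; v <- v[keep]
  p <- v / sum(n * v)
  exp(-sum(n * p * log(p)))
}

# full multinomial engine: one draw per generation over A, B, every live
# lineage and that generation's newly founded single-cell lineages
lineages_multinomial <- function(params, founding, include_phi = TRUE) {
  N <- params$N
  nA <- round((1 - params$phi) * N); nB <- 0
  L <- if (params$phi > 0) round(params$phi * N) else numeric(0)
  Lgen <- if (length(L)) 0L else integer(0)
  founded <- length(L)
  gens <- vector("list", params$horizon + 1)
  div_of <- function(L, Lgen) {
    keep <- if (include_phi) rep(TRUE, length(L)) else Lgen > 0
    if (sum(L[keep]) > 0) shannon_diversity(L[keep]) else NA_real_
  }
  gens[[1]] <- tibble(generation = 0, x_A = nA / N, x_B = nB / N,
                      cnv_total = sum(L) / N, n_lineages = length(L),
                      diversity = div_of(L, Lgen))
  for (g in seq_len(params$horizon)) {
    W <- nA + nB * (1 + params$s_B) + sum(L) * (1 + params$s_C)
    eA <- nA / W; eB <- nB * (1 + params$s_B) / W
    eL <- L * (1 + params$s_C) / W
    lambda <- params$delta_C * eA * N
    n_new <- if (founding == "poisson") rpois(1, lambda) else round(lambda)
    eB <- eB + params$delta_B * eA
    eA <- eA * (1 - params$delta_C - params$delta_B)
    probs <- c(eA, eB, eL, rep(1 / N, n_new))
    cnt <- rmultinom(1, N, probs)[, 1]
    nA <- cnt[1]; nB <- cnt[2]
    L <- cnt[-(1:2)]
    Lgen <- c(Lgen, rep(g, n_new))
    founded <- founded + n_new
    live <- L > 0
    L <- L[live]; Lgen <- Lgen[live]
    gens[[g + 1]] <- tibble(generation = g, x_A = nA / N, x_B = nB / N,
                            cnv_total = sum(L) / N, n_lineages = length(L),
                            diversity = div_of(L, Lgen))
  }
  structure(
    list(generations = dplyr::bind_rows(gens),
         lineages = tibble(founded_gen = Lgen, n_lineages = 1,
                           final_size = L, final_freq = L / N),
         founded_total = founded, params = params,
         founding = founding, growth = "stochastic"),
    class = "cnv_lineages"
  )
}

#' @export
print.cnv_lineages <- function(x, ...) {
  fin <- tail(x$generations, 1)
  cat("<cnv_lineages>\n")
  cat(sprintf("  %s founding, %s growth; %g lineages founded\n",
              x$founding, x$growth, x$founded_total))
  cat(sprintf("  final: %d live lineages, diversity %.4g\n",
              fin$n_lineages, fin$diversity))
  invisible(x)
}

#' Shannon diversity (effective number of lineages)
#'
#' `exp(-sum p_i log p_i)` with frequencies renormalized over the CNV
#' lineages and `0 log 0 = 0`: the number of equally frequent lineages with
#' the same entropy.
#'
#' @param freqs Nonnegative lineage frequencies (or counts).
#' @return Effective number of lineages.
#' @export
#' @examples
#' shannon_diversity(c(0.25, 0.25, 0.25, 0.25))  # 4
#' shannon_diversity(c(0.5, 0.25, 0.25))         # ~2.83
shannon_diversity <- function(freqs) {
  if (any(freqs < 0)) abort("frequencies must be nonnegative")
  s <- sum(freqs)
  if (s == 0) abort("all frequencies are zero")
  p <- freqs[freqs > 0] / s
  exp(-sum(p * log(p)))
}

#' Predicted Shannon-diversity trajectory
#'
#' Repeat the lineage-tracked simulation (optionally across posterior
#' parameter draws) and aggregate the per-generation effective number of
#' lineages as the mean with a 50% interval.
#'
#' @param params A [evolution_params()] object, or `NULL` when `draws` is
#'   given.
#' @param draws Optional data frame of posterior draws (`log10_sC`,
#'   `log10_dC`, `log10_phi`); one simulation is run per draw.
#' @param n_reps Replicate simulations (per draw).
#' @param template [evolution_params()] supplying `N`, `horizon` and fixed
#'   parameters when `draws` is given.
#' @inheritParams simulate_lineages
#' @return Tibble with `generation`, `diversity` (mean), `q25`, `q75`.
#' @export
diversity_trajectory <- function(params = NULL, draws = NULL, n_reps = 5,
                                 founding = "poisson",
                                 growth = "deterministic",
                                 include_phi = TRUE, template = params) {
  if (is.null(params) && is.null(draws))
    abort("provide `params` or `draws`")
  par_list <- if (is.null(draws)) {
    rep(list(params), n_reps)
  } else {
    th <- as_theta_matrix(draws)
    purrr::map(rep(seq_len(nrow(th)), each = n_reps), function(i) {
      evolution_params(
        s_C = 10^th[i, 1], delta_C = 10^th[i, 2], phi = 10^th[i, 3],
        s_B = template$s_B, delta_B = template$delta_B,
        N = template$N, horizon = template$horizon,
        schedule = template$schedule)
    })
  }
  runs <- purrr::map(par_list, function(p)
    simulate_lineages(p, founding, growth,
                      include_phi = include_phi)$generations$diversity)
  m <- do.call(cbind, runs)
  horizon <- par_list[[1]]$horizon
  tibble(
    generation = 0:horizon,
    diversity = rowMeans(m, na.rm = TRUE),
    q25 = apply(m, 1, quantile, 0.25, na.rm = TRUE, names = FALSE),
    q75 = apply(m, 1, quantile, 0.75, na.rm = TRUE, names = FALSE)
  )
}

#' Two-strain competition simulation
#'
#' Eight-genotype Wright-Fisher competition between two strains sharing one
#' chemostat: each strain carries its own CNV parameters, mutation acts only
#' within a strain, selection uses a shared mean fitness, and drift is one
#' multinomial draw per generation over all eight genotypes. Both strains
#' start at proportion 0.5, internally split `(1 - phi)` ancestor / `phi`
#' unreported CNV.
#'
#' @param params_a,params_b [evolution_params()] for the two strains
#'   (`N` must match).
#' @param horizon Competition length in generations (default 116).
#' @param n_reps Stochastic replicates.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return A `cnv_competition`: mean final total frequency of strain A,
#'   per-replicate finals, and the mean per-generation trajectory.
#' @export
#' @examples
#' p <- strain_presets()
#' cmp <- simulate_competition(p$WT, p$ARSD, n_reps = 50)
#' cmp$mean_final
simulate_competition <- function(params_a, params_b, horizon = 116,
                                 n_reps = 1000,
                                 mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params_a, "cnv_params"), inherits(params_b, "cnv_params"))
  if (params_a$N != params_b$N) abort("strains must share the population size")
  N <- params_a$N
  S <- if (mode == "deterministic") 1L else n_reps
  # columns: A, B, C+, C- for strain a then strain b
  x <- matrix(rep(c(0.5 * (1 - params_a$phi), 0, 0, 0.5 * params_a$phi,
                    0.5 * (1 - params_b$phi), 0, 0, 0.5 * params_b$phi),
                  each = S), S, 8)
  w <- c(1, 1 + params_a$s_B, 1 + params_a$s_C, 1 + params_a$s_C,
         1, 1 + params_b$s_B, 1 + params_b$s_C, 1 + params_b$s_C)
  traj <- matrix(NA_real_, horizon + 1, 2)
  traj[1, ] <- c(0.5, 0.5)
  for (g in seq_len(horizon)) {
    xw <- sweep(x, 2, w, `*`)
    x <- xw / rowSums(xw)
    x[, 3] <- x[, 3] + x[, 1] * params_a$delta_C
    x[, 2] <- x[, 2] + x[, 1] * params_a$delta_B
    x[, 1] <- x[, 1] * (1 - params_a$delta_C - params_a$delta_B)
    x[, 7] <- x[, 7] + x[, 5] * params_b$delta_C
    x[, 6] <- x[, 6] + x[, 5] * params_b$delta_B
    x[, 5] <- x[, 5] * (1 - params_b$delta_C - params_b$delta_B)
    if (mode == "stochastic") {
      n <- matrix(0, S, 8)
      rem <- rep(N, S); prem <- rep(1, S)
      for (j in 1:7) {
        p <- ifelse(prem > 0, pmin(pmax(x[, j] / prem, 0), 1), 0)
        n[, j] <- rbinom(S, rem, p)
        rem <- rem - n[, j]
        prem <- prem - x[, j]
      }
      n[, 8] <- rem
      x <- n / N
    }
    fa <- rowSums(x[, 1:4, drop = FALSE])
    traj[g + 1, ] <- c(mean(fa), 1 - mean(fa))
  }
  finals <- rowSums(x[, 1:4, drop = FALSE])
  structure(
    list(mean_final = mean(finals), finals = finals,
         trajectory = tibble(generation = 0:horizon,
                             strain_a = traj[, 1], strain_b = traj[, 2]),
         horizon = horizon, n_reps = S, mode = mode),
    class = "cnv_competition"
  )
}

#' @export
print.cnv_competition <- function(x, ...) {
  cat("<cnv_competition>\n")
  cat(sprintf("  %d generations, %d replicate(s), %s mode\n",
              x$horizon, x$n_reps, x$mode))
  cat(sprintf("  mean final proportion of strain A: %.4f\n", x$mean_final))
  invisible(x)
}

#' @method glance cnv_competition
#' @export
glance.cnv_competition <- function(x, ...) {
  tibble(mean_final = x$mean_final,
         sem = sd(x$finals) / sqrt(length(x$finals)),
         n_reps = x$n_reps, horizon = x$horizon, mode = x$mode)
}
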
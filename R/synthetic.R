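#' Flow-cytometry measurement model
#'
#' Observed proportions are binomial draws of `n_cells` cells at the true
#' reported proportion, emulating a 100,000-cell flow-cytometry sample per
#' timepoint. With `exact = TRUE` the infinite-sample (noiseless) limit is
#' returned.
#'
#' @param reported Numeric vector or matrix of true reported proportions.
#' @param n_cells Cells sampled per measurement.
#' @param exact If `TRUE`, return `reported` unchanged.
#' @return Object of the same shape with measured proportions.
#' @export
measure <- function(reported, n_cells = 1e5, exact = FALSE) {
  stopifnot(all(reported >= 0 & reported <= 1))
  if (exact) return(reported)
  out <- rbinom(length(reported), n_cells, as.vector(reported)) / n_cells
  if (is.matrix(reported)) out <- matrix(out, nrow(reported))
  out
}

#' Generate a synthetic observation cohort
#'
#' Simulate `n_pops` replicate populations evolving under one shared true
#' parameter set (replicates of a strain are founded from the same inoculum),
#' measure each at the schedule, and record the ground truth in a manifest.
#' Each population gets its own sub-seed derived from `seed`, so cohorts are
#' reproducible and populations are independent.
#'
#' @param params A [evolution_params()] object (e.g. a [strain_presets()]
#'   entry) giving the shared true parameters.
#' @param n_pops Number of replicate populations (the study used 5-8).
#' @param seed Integer seed recorded in the manifest.
#' @param strain Strain label attached to the observations.
#' @param n_cells Cells per measurement; `Inf`-like noiseless mode via
#'   `exact = TRUE`.
#' @param exact If `TRUE`, skip measurement noise.
#' @return A list with `observations` (tibble: `population`, `strain`,
#'   `generation`, `prop_reported`, `prop_total`) and `manifest` (tibble of
#'   per-population truth and sub-seeds).
#' @export
#' @examples
#' cohort <- generate_cohort(strain_presets()$WT, n_pops = 2, seed = 1)
#' head(cohort$observations)
generate_cohort <- function(params, n_pops = 6, seed, strain = "synthetic",
                            n_cells = 1e5, exact = FALSE) {
  stopifnot(inherits(params, "cnv_params"), n_pops >= 1)
  sub_seeds <- (as.integer(seed) %% 1000000L) * 1000L + seq_len(n_pops)
  obs <- purrr::map_dfr(seq_len(n_pops), function(i) {
    with_seed(sub_seeds[i], {
      sim <- sim_reported_batch(
        params$s_C, params$delta_C, params$phi, params$s_B, params$delta_B,
        N = params$N, horizon = params$horizon, schedule = params$schedule)
      tibble(
        population = paste0(strain, "_", i),
        strain = strain,
        generation = params$schedule,
        prop_reported = as.vector(measure(sim$reported, n_cells, exact)),
        prop_total = as.vector(sim$total)
      )
    })
  })
  manifest <- tibble(
    population = paste0(strain, "_", seq_len(n_pops)),
    strain = strain,
    log10_sC = log10(params$s_C),
    log10_dC = log10(params$delta_C),
    log10_phi = log10(params$phi),
    seed = sub_seeds,
    n_cells = n_cells,
    schedule = paste(params$schedule, collapse = ";")
  )
  list(observations = obs, manifest = manifest)
}
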
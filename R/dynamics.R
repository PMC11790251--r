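#' Generation of CNV appearance
#'
#' The generation of the first sampled timepoint that begins a run of at least
#' `consecutive` successive sampled timepoints all strictly above `threshold`.
#' "Three consecutive generations" is interpreted as three consecutive
#' *sampled timepoints*, since measurements are taken every 8-10 generations.
#'
#' @param generation Sorted numeric vector of sampled generations.
#' @param proportion CNV proportion at each sampled generation, in \[0, 1\].
#' @param threshold Appearance threshold (default 10%).
#' @param consecutive Required run length (default 3 timepoints).
#' @return The appearance generation, or `NA` if no qualifying run exists.
#' @export
#' @examples
#' appearance_generation(seq(0, 50, 10), c(0, .01, .05, .12, .2, .4))
appearance_generation <- function(generation, proportion,
                                  threshold = 0.1, consecutive = 3) {
  check_series(generation, proportion)
  n <- length(proportion)
  if (n < consecutive) return(NA_real_)
  above <- proportion > threshold
  run <- 0
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1 else 0
    if (run == consecutive) return(generation[i - consecutive + 1])
  }
  NA_real_
}

#' Per-generation increase in CNV proportion
#'
#' Ordinary least-squares slope of `log(p / (1 - p))` against generation over
#' the rise window. Because the logit of a logistic curve is linear in time
#' with slope equal to the selection coefficient, this estimates the
#' per-generation rate of increase. Proportions are clamped to
#' `[1/(2 n_cells), 1 - 1/(2 n_cells)]`, reflecting the resolution of a
#' 100,000-cell flow-cytometry sample.
#'
#' @inheritParams appearance_generation
#' @param window Optional numeric `c(lo, hi)` generation range. By default the
#'   window runs from the last timepoint below `threshold` to the first
#'   timepoint exceeding `rise_frac` of the series maximum.
#' @param threshold Lower anchor of the automatic window (default 0.1).
#' @param rise_frac Upper anchor of the automatic window as a fraction of the
#'   series maximum (default 0.5, i.e. the rise up to half-maximum, where the
#'   log-linear approximation holds).
#' @param n_cells Assay sample size determining the logit clamp.
#' @return Slope (per generation).
#' @export
increase_per_generation <- function(generation, proportion, window = NULL,
                                    threshold = 0.1, rise_frac = 0.5,
                                    n_cells = 1e5) {
  check_series(generation, proportion)
  if (is.null(window)) {
    below <- which(proportion < threshold)
    lo <- if (length(below)) generation[max(below)] else generation[1]
    hi_idx <- which(proportion >= rise_frac * max(proportion))[1]
    hi <- generation[hi_idx]
    window <- c(lo, hi)
  }
  keep <- generation >= window[1] & generation <= window[2]
  if (sum(keep) < 2) abort("fewer than 2 timepoints in the regression window")
  eps <- 1 / (2 * n_cells)
  p <- pmin(pmax(proportion[keep], eps), 1 - eps)
  y <- log(p / (1 - p))
  unname(coef(lm.fit(cbind(1, generation[keep]), y))[2])
}

#' Generation of CNV equilibrium
#'
#' Scans sliding windows of `window_width` successive sampled timepoints
#' starting at or after `start` and returns the first window-start generation
#' whose OLS slope of the raw proportion against generation is below
#' `slope_threshold` in magnitude.
#'
#' @inheritParams appearance_generation
#' @param slope_threshold Flatness criterion on the raw proportion scale
#'   (default 0.005 per generation).
#' @param start First generation to consider (typically the appearance
#'   generation; defaults to the first sampled generation).
#' @param window_width Number of timepoints per window (default 3).
#' @return The equilibrium generation, or `NA` if the series never flattens.
#' @export
equilibrium_generation <- function(generation, proportion,
                                   slope_threshold = 0.005,
                                   start = min(generation),
                                   window_width = 3) {
  check_series(generation, proportion)
  idx <- which(generation >= start)
  n <- length(generation)
  for (i in idx) {
    j <- i + window_width - 1
    if (j > n) break
    sl <- coef(lm.fit(cbind(1, generation[i:j]), proportion[i:j]))[2]
    if (abs(sl) < slope_threshold) return(generation[i])
  }
  NA_real_
}

check_series <- function(generation, proportion) {
  if (length(generation) != length(proportion))
    abort("`generation` and `proportion` must have equal length")
  if (is.unsorted(generation, strictly = TRUE))
    abort("`generation` must be strictly increasing")
  if (any(proportion < 0 | proportion > 1, na.rm = TRUE))
    abort("`proportion` must lie in [0, 1]")
  invisible(NULL)
}

#' Summarize CNV dynamics per population
#'
#' Compute the three dynamics statistics (appearance generation, logit slope
#' of the rise, equilibrium generation) for each population in a trajectory
#' table. The equilibrium scan starts at the appearance generation; when a
#' population never passes the appearance threshold both the appearance and
#' equilibrium generations are `NA`.
#'
#' @param data A data frame with columns `population`, `generation` and a
#'   proportion column (plus optionally `strain`).
#' @param proportion Name of the proportion column (default `prop_reported`).
#' @param threshold,consecutive Passed to [appearance_generation()].
#' @param slope_threshold,window_width Passed to [equilibrium_generation()].
#' @return A tibble with one row per population.
#' @export
#' @examples
#' presets <- strain_presets()
#' cohort <- generate_cohort(presets$WT, n_pops = 3, seed = 1, strain = "WT")
#' summarize_dynamics(cohort$observations)
summarize_dynamics <- function(data, proportion = "prop_reported",
                               threshold = 0.1, consecutive = 3,
                               slope_threshold = 0.005, window_width = 3) {
  stopifnot(all(c("population", "generation", proportion) %in% names(data)))
  grp <- intersect(c("population", "strain"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(.data$generation, .by_group = TRUE) |>
    dplyr::summarise(
      appearance_generation = appearance_generation(
        .data$generation, .data[[proportion]], threshold, consecutive),
      increase_per_generation = increase_per_generation(
        .data$generation, .data[[proportion]], threshold = threshold),
      equilibrium_generation = if (is.na(appearance_generation)) NA_real_ else
        equilibrium_generation(
          .data$generation, .data[[proportion]], slope_threshold,
          start = appearance_generation, window_width = window_width),
      .groups = "drop"
    )
}
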
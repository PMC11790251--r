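#' Evolutionary model parameters
#'
#' Bundle the parameters of the four-genotype chemostat Wright-Fisher model.
#' The four genotypes are A (ancestor), B (carrier of a non-CNV beneficial
#' mutation), C+ (GAP1 CNV with an amplified fluorescent reporter, i.e. the
#' *reported* CNV class) and C- (GAP1 CNV without reporter amplification,
#' invisible to the flow-cytometry assay).
#'
#' @param s_C Selection coefficient of the CNV genotypes (per generation).
#' @param delta_C GAP1 CNV formation rate (per genome per generation).
#' @param s_B Selection coefficient of other beneficial mutations.
#' @param delta_B Formation rate of other beneficial mutations.
#' @param phi Proportion of cells carrying an unreported CNV (genotype C-)
#'   at generation 0. C- is never generated after generation 0.
#' @param N Population size (cells) held constant by the chemostat.
#' @param horizon Number of generations to simulate.
#' @param schedule Strictly increasing integer vector of sampled generations
#'   within `[0, horizon]`; defaults to [default_schedule()].
#'
#' @return An object of class `cnv_params` (a named list).
#' @seealso [strain_presets()] for the parameter sets of the four strains.
#' @export
#' @examples
#' evolution_params(s_C = 0.15, delta_C = 1e-4, phi = 1e-4)
evolution_params <- function(s_C, delta_C, s_B = 1e-3, delta_B = 1e-5,
                             phi = 1e-5, N = 1e8, horizon = 137,
                             schedule = default_schedule(horizon)) {
  stopifnot(is.numeric(s_C), is.numeric(delta_C), length(s_C) == 1)
  if (s_C < 0 || s_B < 0) abort("selection coefficients must be nonnegative")
  if (delta_C < 0 || delta_B < 0 || delta_C + delta_B > 1)
    abort("formation rates must satisfy 0 <= delta_C + delta_B <= 1")
  if (phi < 0 || phi > 1) abort("`phi` must be in [0, 1]")
  if (N < 1 || N != round(N)) abort("`N` must be a positive integer")
  if (!all(diff(schedule) > 0) || any(schedule < 0) || any(schedule > horizon))
    abort("`schedule` must be strictly increasing within [0, horizon]")
  structure(
    list(s_C = s_C, delta_C = delta_C, s_B = s_B, delta_B = delta_B,
         phi = phi, N = N, horizon = horizon, schedule = as.integer(schedule)),
    class = "cnv_params"
  )
}

#' @export
print.cnv_params <- function(x, ...) {
  cat("<cnv_params>\n")
  cat(sprintf("  s_C = %g, delta_C = %g, s_B = %g, delta_B = %g, phi = %g\n",
              x$s_C, x$delta_C, x$s_B, x$delta_B, x$phi))
  cat(sprintf("  N = %g, horizon = %d, %d sampled generations\n",
              x$N, x$horizon, length(x$schedule)))
  invisible(x)
}

#' Default observation schedule
#'
#' Sixteen timepoints evenly spaced from generation 8 to the horizon
#' (~8.6-generation spacing for the default 137-generation experiment),
#' emulating flow-cytometry sampling every 8-10 generations.
#'
#' @param horizon Final generation.
#' @param n_points Number of sampled timepoints.
#' @param first First sampled generation.
#' @return Integer vector of sampled generations.
#' @export
default_schedule <- function(horizon = 137, n_points = 16, first = 8) {
  first <- min(first, horizon)
  unique(round(seq(first, horizon, length.out = n_points)))
}

#' Prior support of the inferred parameters
#'
#' The inference operates on theta = (log10 s_C, log10 delta_C, log10 phi)
#' with independent uniform priors on these log10 intervals.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
prior_support <- function() {
  tibble(
    parameter = c("log10_sC", "log10_dC", "log10_phi"),
    lower = c(-2, -7, -8),
    upper = c(0, -0.3, -2)
  )
}

# internal bounds as vectors
.theta_lower <- c(log10_sC = -2, log10_dC = -7, log10_phi = -8)
.theta_upper <- c(log10_sC = 0, log10_dC = -0.3, log10_phi = -2)
.theta_names <- c("log10_sC", "log10_dC", "log10_phi")

#' Strain parameter presets
#'
#' Parameter sets for the wild-type strain and the three genomic-architecture
#' deletion strains, using the published collective maximum a posteriori
#' estimates of the CNV selection coefficient and formation rate for each
#' strain. These are model *inputs* (obtained from flow-cytometry data that
#' this package does not ship), not quantities the package re-estimates.
#' Strain names are ASCII aliases: `LTRD`, `ARSD` and `ALLD` carry a deletion
#' (Delta) suffix in display form.
#'
#' @param phi Initial unreported-CNV proportion used for every strain; only a
#'   plausible range (4e-6 to 1.6e-4) is published per strain.
#' @param N,horizon Population size and experiment length.
#' @return Named list of [evolution_params()] objects
#'   (`WT`, `LTRD`, `ARSD`, `ALLD`).
#' @export
#' @examples
#' strain_presets()$WT$delta_C
strain_presets <- function(phi = 1e-5, N = 1e8, horizon = 137) {
  mk <- function(s_C, delta_C) {
    evolution_params(s_C = s_C, delta_C = delta_C, s_B = 1e-3, delta_B = 1e-5,
                     phi = phi, N = N, horizon = horizon)
  }
  list(
    WT   = mk(0.182, 4.5e-5),
    LTRD = mk(0.182, 1.0e-5),
    ARSD = mk(0.146, 2.4e-6),
    ALLD = mk(0.126, 1.0e-5)
  )
}

#' Display names for strain aliases
#' @param strain Character vector of ASCII strain aliases.
#' @return Character vector with Unicode Delta display names.
#' @export
strain_display <- function(strain) {
  map <- c(WT = "WT", LTRD = "LTRΔ", ARSD = "ARSΔ", ALLD = "ALLΔ")
  out <- unname(map[strain])
  out[is.na(out)] <- strain[is.na(out)]
  out
}
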
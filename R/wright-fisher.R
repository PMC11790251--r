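#' Initial genotype state
#'
#' At generation 0 only the ancestor (A) and the unreported CNV genotype (C-)
#' are present, with frequencies `1 - phi` and `phi`.
#'
#' @param phi Initial proportion of genotype C-.
#' @return Named numeric vector `c(x_A, x_B, x_Cplus, x_Cminus)` summing to 1.
#' @export
#' @examples
#' init_state(1e-4)
init_state <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1 || is.na(phi) || phi < 0 || phi > 1)
    abort("`phi` must be a single value in [0, 1]")
  c(x_A = 1 - phi, x_B = 0, x_Cplus = 0, x_Cminus = phi)
}

validate_state <- function(state, tol = 1e-9) {
  if (length(state) != 4 || any(state < -tol) || abs(sum(state) - 1) > 1e-6)
    abort("invalid genotype state: frequencies must be in [0,1] and sum to 1")
  invisible(state)
}

#' Selection stage
#'
#' Multiply each genotype frequency by its relative fitness and renormalize by
#' the mean fitness: `w_A = 1`, `w_B = 1 + s_B`, `w_C+ = w_C- = 1 + s_C`.
#'
#' @param state Genotype state, as from [init_state()].
#' @param params A [evolution_params()] object.
#' @return Updated genotype state.
#' @export
step_selection <- function(state, params) {
  validate_state(state)
  w <- c(1, 1 + params$s_B, 1 + params$s_C, 1 + params$s_C)
  xw <- state * w
  xw / sum(xw)
}

#' Mutation stage
#'
#' Only the ancestor mutates: a fraction `delta_C` of A becomes C+ and a
#' fraction `delta_B` becomes B. C- is never generated after generation 0 and
#' there are no double mutants or back-mutations.
#'
#' @inheritParams step_selection
#' @return Updated genotype state (sum preserved).
#' @export
step_mutation <- function(state, params) {
  validate_state(state)
  if (params$delta_C + params$delta_B > 1)
    abort("delta_C + delta_B must not exceed 1")
  out <- state
  out["x_Cplus"] <- state["x_Cplus"] + state["x_A"] * params$delta_C
  out["x_B"] <- state["x_B"] + state["x_A"] * params$delta_B
  out["x_A"] <- state["x_A"] * (1 - params$delta_C - params$delta_B)
  out
}

#' Drift stage
#'
#' Resample the next generation as one multinomial draw of `N` cells over the
#' four genotypes. In deterministic mode the expectation (the state itself) is
#' returned, which disables drift.
#'
#' @inheritParams step_selection
#' @param N Population size (cells).
#' @param deterministic If `TRUE`, return the expectation instead of sampling.
#' @return Updated genotype state.
#' @export
step_drift <- function(state, N, deterministic = FALSE) {
  validate_state(state)
  if (deterministic) return(state)
  p <- pmax(state, 0)
  counts <- rmultinom(1, size = N, prob = p)[, 1]
  out <- counts / N
  names(out) <- names(state)
  out
}

#' Simulate a CNV trajectory
#'
#' Run the four-genotype Wright-Fisher model for `params$horizon` generations,
#' applying selection, mutation and drift in that order each generation, and
#' record the reported CNV proportion (`x_Cplus`) and total CNV proportion
#' (`x_Cplus + x_Cminus`) at every generation.
#'
#' @param params A [evolution_params()] object.
#' @param mode `"stochastic"` (multinomial drift) or `"deterministic"`
#'   (drift disabled; used for oracles and fast checks).
#' @param keep_states If `TRUE`, include the four genotype frequencies.
#' @return A tibble with columns `generation`, `prop_reported`, `prop_total`
#'   and, if requested, `x_A`, `x_B`, `x_Cplus`, `x_Cminus`.
#' @export
#' @examples
#' p <- evolution_params(s_C = 0.15, delta_C = 1e-4, phi = 1e-4)
#' traj <- simulate_trajectory(p, mode = "deterministic")
#' tail(traj)
simulate_trajectory <- function(params,
                                mode = c("stochastic", "deterministic"),
                                keep_states = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "cnv_params"))
  state <- init_state(params$phi)
  n <- params$horizon + 1
  states <- matrix(NA_real_, n, 4, dimnames = list(NULL, names(state)))
  states[1, ] <- state
  for (g in seq_len(params$horizon)) {
    state <- step_selection(state, params)
    state <- step_mutation(state, params)
    state <- step_drift(state, params$N, deterministic = mode == "deterministic")
    states[g + 1, ] <- state
  }
  out <- tibble(
    generation = 0:params$horizon,
    prop_reported = states[, "x_Cplus"],
    prop_total = states[, "x_Cplus"] + states[, "x_Cminus"]
  )
  if (keep_states) out <- dplyr::bind_cols(out, as_tibble(states))
  out
}

#' Closed-form total CNV proportion without mutation or drift
#'
#' With formation rates set to zero and drift disabled, the total CNV
#' proportion follows the logistic form
#' `phi * exp(s_C * t) / (1 - phi + phi * exp(s_C * t))` (relative fitness
#' `1 + s_C` per discrete generation, so `exp` is replaced by powers of
#' `1 + s_C`). Used as an independent oracle for the simulator.
#'
#' @param t Generations (vector).
#' @param s_C Selection coefficient.
#' @param phi Initial CNV proportion.
#' @param discrete If `TRUE` (default) use the exact discrete-generation form
#'   `(1 + s_C)^t`; otherwise the continuous `exp(s_C t)` approximation.
#' @return Total CNV proportion at each `t`.
#' @export
logistic_total <- function(t, s_C, phi, discrete = TRUE) {
  g <- if (discrete) (1 + s_C)^t else exp(s_C * t)
  phi * g / (1 - phi + phi * g)
}

#' Batch simulation of CNV proportions at a schedule
#'
#' Vectorized Wright-Fisher engine: simulates one trajectory per parameter
#' set simultaneously (drift via sequential binomial splitting of the
#' multinomial draw) and records proportions only at the scheduled
#' generations. This is the engine behind [build_training_set()]; it matches
#' [simulate_trajectory()] distributionally.
#'
#' @param s_C,delta_C,phi Parameter vectors of equal length (one entry per
#'   simulation).
#' @param s_B,delta_B,N,horizon Shared scalar settings.
#' @param schedule Generations at which proportions are recorded.
#' @param stochastic If `FALSE`, run the deterministic expectation.
#' @return List with matrices `reported` and `total`
#'   (`length(s_C)` x `length(schedule)`).
#' @export
sim_reported_batch <- function(s_C, delta_C, phi, s_B = 1e-3, delta_B = 1e-5,
                               N = 1e8, horizon = 137,
                               schedule = default_schedule(horizon),
                               stochastic = TRUE) {
  S <- length(s_C)
  stopifnot(length(delta_C) == S, length(phi) == S)
  xA <- 1 - phi
  xB <- numeric(S)
  xCp <- numeric(S)
  xCm <- phi
  reported <- matrix(NA_real_, S, length(schedule))
  total <- matrix(NA_real_, S, length(schedule))
  clamp01 <- function(p) pmin(pmax(p, 0), 1)
  k0 <- match(0L, schedule)
  if (!is.na(k0)) { reported[, k0] <- xCp; total[, k0] <- xCp + xCm }
  for (g in seq_len(horizon)) {
    wbar <- xA + xB * (1 + s_B) + (xCp + xCm) * (1 + s_C)
    xB <- xB * (1 + s_B) / wbar
    xCp <- xCp * (1 + s_C) / wbar
    xCm <- xCm * (1 + s_C) / wbar
    xA <- pmax(1 - xB - xCp - xCm, 0)
    xCp <- xCp + xA * delta_C
    xB <- xB + xA * delta_B
    xA <- xA * (1 - delta_C - delta_B)
    if (stochastic) {
      nA <- rbinom(S, N, clamp01(xA))
      pB <- ifelse(xA < 1, xB / (1 - xA), 0)
      nB <- rbinom(S, N - nA, clamp01(pB))
      pCp <- ifelse(xA + xB < 1, xCp / (1 - xA - xB), 0)
      nCp <- rbinom(S, N - nA - nB, clamp01(pCp))
      nCm <- N - nA - nB - nCp
      xA <- nA / N; xB <- nB / N; xCp <- nCp / N; xCm <- nCm / N
    }
    k <- match(g, schedule)
    if (!is.na(k)) { reported[, k] <- xCp; total[, k] <- xCp + xCm }
  }
  list(reported = reported, total = total)
}
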
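#' Sample parameters from the prior
#'
#' Independent uniform draws of theta = (log10 s_C, log10 delta_C, log10 phi)
#' on the support given by [prior_support()].
#'
#' @param n Number of draws.
#' @return Tibble with columns `log10_sC`, `log10_dC`, `log10_phi`.
#' @export
sample_prior <- function(n) {
  stopifnot(n >= 1)
  tibble(
    log10_sC = runif(n, .theta_lower[1], .theta_upper[1]),
    log10_dC = runif(n, .theta_lower[2], .theta_upper[2]),
    log10_phi = runif(n, .theta_lower[3], .theta_upper[3])
  )
}

#' Build a training set for simulation-based inference
#'
#' For each prior draw, simulate a stochastic trajectory of the evolutionary
#' model, read the reported CNV proportion at the observation schedule, and
#' apply the binomial measurement model. The other-beneficial-mutation
#' parameters are fixed (`s_B` = 1e-3, `delta_B` = 1e-5).
#'
#' @param n_sims Number of simulations (prior draws).
#' @param schedule Observation schedule (generations).
#' @param n_cells Cells per measurement; set `noise = FALSE` to condition on
#'   noiseless proportions.
#' @param noise Apply the binomial measurement model (default `TRUE`).
#' @param s_B,delta_B Fixed non-CNV beneficial mutation parameters.
#' @param N,horizon Population size and number of generations.
#' @param seed Optional integer seed (recorded in the result).
#' @return A `cnv_training_set`: list with `theta` (tibble), `x` (matrix of
#'   observations, one row per draw), `schedule`, `n_cells`, `seed`.
#' @export
build_training_set <- function(n_sims = 10000, schedule = default_schedule(),
                               n_cells = 1e5, noise = TRUE,
                               s_B = 1e-3, delta_B = 1e-5,
                               N = 1e8, horizon = 137, seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  theta <- sample_prior(n_sims)
  sim <- sim_reported_batch(
    10^theta$log10_sC, 10^theta$log10_dC, 10^theta$log10_phi,
    s_B = s_B, delta_B = delta_B, N = N, horizon = horizon,
    schedule = schedule)
  x <- if (noise) measure(sim$reported, n_cells) else sim$reported
  structure(
    list(theta = theta, x = x, schedule = schedule, n_cells = n_cells,
         seed = seed),
    class = "cnv_training_set"
  )
}

logit_clamped <- function(p, n_cells = 1e5) {
  eps <- 1 / (2 * n_cells)
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Train the amortized conditional density estimator
#'
#' Fits a Gaussian-mixture conditional density estimator: observations are
#' logit-transformed and projected onto their leading principal components,
#' a full-covariance Gaussian mixture is fitted by maximum likelihood (EM)
#' to the joint of parameters and features, and posteriors for new
#' observations are obtained by analytic conditioning of the mixture — so a
#' single training run amortizes inference over any number of observations.
#' A small uniform "defensive" component over the prior box guards against
#' vanishing density for atypical observations.
#'
#' @param training_set A `cnv_training_set` from [build_training_set()].
#' @param n_components Number of mixture components.
#' @param n_pc Number of principal components of the logit observations.
#' @param defensive_weight Mixture weight of the uniform component.
#' @param min_sd Bandwidth floor: minimum standard deviation (log10 units) of
#'   any principal axis of a conditional posterior component, so that
#'   posterior densities stay resolvable on the Riemann grids used by the
#'   collective module.
#' @param init_subset Size of the random subset used to initialize EM.
#' @param seed Optional seed controlling EM initialization.
#' @return A `cnv_estimator`.
#' @export
train_density_estimator <- function(training_set, n_components = 15,
                                    n_pc = 6, defensive_weight = 0.005,
                                    min_sd = 0.035, init_subset = 2000,
                                    seed = NULL) {
  stopifnot(inherits(training_set, "cnv_training_set"))
  if (nrow(training_set$x) < 1000)
    abort("need at least 1000 training pairs")
  if (!is.null(seed)) local_seed(seed)
  y <- logit_clamped(training_set$x, training_set$n_cells)
  if (any(!is.finite(y)) || max(apply(y, 2, sd)) < 1e-12)
    abort("degenerate training set: observations are constant or non-finite")
  pc <- prcomp(y, rank. = n_pc)
  z <- cbind(as.matrix(training_set$theta), pc$x[, seq_len(n_pc), drop = FALSE])
  init <- list(subset = sample.int(nrow(z), min(init_subset, nrow(z))))
  fit <- Mclust(z, G = n_components, modelNames = "VVV",
                initialization = init, verbose = FALSE)
  if (is.null(fit)) abort("mixture fitting failed")
  structure(
    list(
      pro = fit$parameters$pro,
      mean = fit$parameters$mean,
      sigma = fit$parameters$variance$sigma,
      pc_center = pc$center,
      pc_rotation = pc$rotation[, seq_len(n_pc), drop = FALSE],
      n_pc = n_pc,
      defensive_weight = defensive_weight,
      min_sd = min_sd,
      schedule = training_set$schedule,
      n_cells = training_set$n_cells,
      n_train = nrow(training_set$x),
      loglik = fit$loglik,
      bic = fit$bic,
      seed = seed,
      version = 1L
    ),
    class = "cnv_estimator"
  )
}

#' @export
print.cnv_estimator <- function(x, ...) {
  cat("<cnv_estimator>\n")
  cat(sprintf("  Gaussian-mixture conditional density estimator (%d components)\n",
              length(x$pro)))
  cat(sprintf("  trained on %d simulations, %d logit-PCA features, loglik %.1f\n",
              x$n_train, x$n_pc, x$loglik))
  invisible(x)
}

#' @method glance cnv_estimator
#' @export
glance.cnv_estimator <- function(x, ...) {
  tibble(n_train = x$n_train, n_components = length(x$pro), n_pc = x$n_pc,
         defensive_weight = x$defensive_weight, loglik = x$loglik, bic = x$bic)
}

# project observations (rows) onto the estimator's feature space
featurize <- function(estimator, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(estimator$schedule))
    abort(sprintf("observation length %d does not match training schedule length %d",
                  ncol(x), length(estimator$schedule)))
  y <- logit_clamped(x, estimator$n_cells)
  sweep(y, 2, estimator$pc_center) %*% estimator$pc_rotation
}

# floor the eigenvalues of a covariance matrix at sd_min^2
floor_cov <- function(S, sd_min) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= sd_min^2) return(S)
  v <- pmax(e$values, sd_min^2)
  e$vectors %*% (v * t(e$vectors))
}

# conditional Gaussian mixture over theta given feature vector u
conditional_mixture <- function(estimator, u) {
  K <- length(estimator$pro)
  d <- 3L
  lw <- numeric(K)
  cmean <- matrix(0, d, K)
  ccov <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    m <- estimator$mean[, k]
    S <- estimator$sigma[, , k]
    ch <- chol(S[-(1:d), -(1:d)])
    diff <- u - m[-(1:d)]
    sol <- backsolve(ch, forwardsolve(t(ch), diff))
    lw[k] <- log(estimator$pro[k]) - sum(log(diag(ch))) -
      0.5 * sum(diff * sol) - 0.5 * length(u) * log(2 * pi)
    S_tu <- S[1:d, -(1:d), drop = FALSE]
    A <- S_tu %*% chol2inv(ch)
    cmean[, k] <- m[1:d] + A %*% diff
    cc <- S[1:d, 1:d] - A %*% t(S_tu)
    ccov[, , k] <- floor_cov((cc + t(cc)) / 2, estimator$min_sd %||% 0)
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  list(w = w / sum(w), mean = cmean, cov = ccov)
}

# draw n points from the untruncated conditional mixture
sample_mixture_raw <- function(mix, n) {
  K <- length(mix$w)
  ks <- sample.int(K, n, replace = TRUE, prob = mix$w)
  out <- matrix(0, n, 3)
  for (k in unique(ks)) {
    idx <- which(ks == k)
    ch <- chol(mix$cov[, , k])
    z <- matrix(rnorm(3 * length(idx)), length(idx), 3)
    out[idx, ] <- sweep(z %*% ch, 2, mix$mean[, k], `+`)
  }
  out
}

in_box <- function(pts) {
  pts[, 1] >= .theta_lower[1] & pts[, 1] <= .theta_upper[1] &
    pts[, 2] >= .theta_lower[2] & pts[, 2] <= .theta_upper[2] &
    pts[, 3] >= .theta_lower[3] & pts[, 3] <= .theta_upper[3]
}

.box_volume <- function() prod(.theta_upper - .theta_lower)

# mass of the untruncated mixture inside the prior box; fixed-seed Monte
# Carlo so the normalization is deterministic given the mixture
mixture_box_mass <- function(mix, n = 5e4) {
  with_seed(191919L, mean(in_box(sample_mixture_raw(mix, n))))
}

#' Posterior for a single observation
#'
#' Condition the trained estimator on one observation vector: the result is a
#' Gaussian-mixture density over theta (log10 coordinates), truncated to the
#' prior support and mixed with the estimator's small uniform defensive
#' component. No retraining is needed (posterior amortization).
#'
#' @param estimator A `cnv_estimator`.
#' @param observation Numeric vector of reported CNV proportions at the
#'   training schedule (length must match).
#' @return A `cnv_posterior` with a sampler ([posterior_sample()]) and
#'   pointwise normalized log density ([posterior_logpdf()]).
#' @export
individual_posterior <- function(estimator, observation) {
  stopifnot(inherits(estimator, "cnv_estimator"))
  if (any(observation < 0 | observation > 1))
    abort("observation proportions must lie in [0, 1]")
  u <- featurize(estimator, observation)[1, ]
  mix <- conditional_mixture(estimator, u)
  m_in <- mixture_box_mass(mix)
  w0 <- estimator$defensive_weight
  structure(
    list(mix = mix, box_mass = m_in, defensive_weight = w0,
         norm = (1 - w0) * m_in + w0),
    class = "cnv_posterior"
  )
}

#' @export
print.cnv_posterior <- function(x, ...) {
  cat("<cnv_posterior>\n")
  cat(sprintf("  %d-component conditional Gaussian mixture on log10(s_C, delta_C, phi)\n",
              length(x$mix$w)))
  cat(sprintf("  prior-box mass of untruncated mixture: %.3f\n", x$box_mass))
  invisible(x)
}

#' Sample from a posterior
#'
#' @param posterior A `cnv_posterior`.
#' @param n Number of draws.
#' @return Tibble of draws (columns `log10_sC`, `log10_dC`, `log10_phi`),
#'   all within the prior support.
#' @export
posterior_sample <- function(posterior, n) {
  stopifnot(inherits(posterior, "cnv_posterior"))
  w0 <- posterior$defensive_weight
  z <- posterior$norm
  n_unif <- rbinom(1, n, w0 / z)
  n_mix <- n - n_unif
  lo <- .theta_lower; hi <- .theta_upper
  out <- matrix(runif(3 * n_unif, rep(lo, each = n_unif), rep(hi, each = n_unif)),
                n_unif, 3)
  if (n_mix > 0) {
    acc <- max(posterior$box_mass, 0.02)
    got <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(got) < n_mix && tries < 80) {
      m <- min(ceiling((n_mix - nrow(got)) / acc) + 50, 2e5)
      pts <- sample_mixture_raw(posterior$mix, m)
      got <- rbind(got, pts[in_box(pts), , drop = FALSE])
      tries <- tries + 1
    }
    if (nrow(got) < n_mix) {
      extra <- n_mix - nrow(got)
      got <- rbind(got, matrix(runif(3 * extra, rep(lo, each = extra),
                                     rep(hi, each = extra)), extra, 3))
    }
    out <- rbind(out, got[seq_len(n_mix), , drop = FALSE])
  }
  colnames(out) <- .theta_names
  as_tibble(out)
}

#' Normalized posterior log density
#'
#' Log density over the prior support in log10-parameter coordinates;
#' `-Inf` outside the support.
#'
#' @param posterior A `cnv_posterior`.
#' @param theta Matrix/data frame of points (columns log10_sC, log10_dC,
#'   log10_phi) or a single length-3 vector.
#' @return Numeric vector of log densities.
#' @export
posterior_logpdf <- function(posterior, theta) {
  stopifnot(inherits(posterior, "cnv_posterior"))
  pts <- as_theta_matrix(theta)
  mix <- posterior$mix
  dens <- numeric(nrow(pts))
  for (k in seq_along(mix$w)) {
    ch <- chol(mix$cov[, , k])
    df <- sweep(pts, 2, mix$mean[, k])
    q <- rowSums((df %*% chol2inv(ch)) * df)
    dens <- dens + mix$w[k] *
      exp(-0.5 * q - sum(log(diag(ch))) - 1.5 * log(2 * pi))
  }
  w0 <- posterior$defensive_weight
  out <- log((1 - w0) * dens + w0 / .box_volume()) - log(posterior$norm)
  out[!in_box(pts)] <- -Inf
  out
}

as_theta_matrix <- function(theta) {
  if (is.data.frame(theta)) theta <- as.matrix(theta[, .theta_names])
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  stopifnot(ncol(theta) == 3)
  unname(theta)
}

#' Maximum a posteriori estimate
#'
#' Local Nelder-Mead refinement of the posterior log density, started from
#' the best of `n_draws` posterior samples.
#'
#' @param posterior A `cnv_posterior`.
#' @param n_draws Number of posterior samples screened for the start point.
#' @return One-row tibble with the MAP coordinates and `log_density`.
#' @export
map_estimate <- function(posterior, n_draws = 10000) {
  s <- as.matrix(posterior_sample(posterior, n_draws))
  lp <- posterior_logpdf(posterior, s)
  start <- s[which.max(lp), ]
  f <- function(th) {
    if (!all(th >= .theta_lower & th <= .theta_upper)) return(1e10)
    -posterior_logpdf(posterior, th)
  }
  opt <- optim(start, f, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 2000))
  best <- if (opt$value <= -max(lp)) opt$par else start
  out <- as_tibble(as.list(setNames(best, .theta_names)))
  out$log_density <- posterior_logpdf(posterior, best)
  out
}

#' Marginal highest-density intervals
#'
#' Shortest interval containing `mass` of the samples, per column.
#'
#' @param samples Data frame or matrix of posterior samples.
#' @param mass Probability mass (default 0.95).
#' @return Tibble with `parameter`, `lower`, `upper`.
#' @export
marginal_hdi <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) abort("`mass` must be in (0, 1)")
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) abort("need at least 2 samples")
  res <- apply(samples, 2, hdi_vector, mass = mass)
  tibble(parameter = colnames(samples) %||% paste0("V", seq_len(ncol(samples))),
         lower = unname(res[1, ]), upper = unname(res[2, ]))
}

hdi_vector <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior coverage of the true parameters
#'
#' Calibration check: the fraction of held-out (theta, observation) pairs
#' whose true theta falls inside the posterior marginal HDIs of nominal mass
#' `mass`. Reports per-coordinate coverage and the joint fraction for which
#' all three coordinates are covered simultaneously.
#'
#' @param estimator A `cnv_estimator`.
#' @param test_set A `cnv_training_set` of held-out pairs (not used in
#'   training).
#' @param mass Nominal HDI mass.
#' @param n_samples Posterior draws per observation.
#' @return Tibble with one row per coordinate plus a `joint` row.
#' @export
coverage <- function(estimator, test_set, mass = 0.95, n_samples = 1500) {
  stopifnot(inherits(test_set, "cnv_training_set"))
  n <- nrow(test_set$x)
  if (n < 1) abort("empty test set")
  truth <- as.matrix(test_set$theta)
  hit <- matrix(NA, n, 3, dimnames = list(NULL, .theta_names))
  for (i in seq_len(n)) {
    post <- individual_posterior(estimator, test_set$x[i, ])
    s <- as.matrix(posterior_sample(post, n_samples))
    for (j in 1:3) {
      h <- hdi_vector(s[, j], mass)
      hit[i, j] <- truth[i, j] >= h[1] && truth[i, j] <= h[2]
    }
  }
  tibble(
    parameter = c(.theta_names, "joint"),
    coverage = c(colMeans(hit), mean(rowSums(hit) == 3)),
    n = n, mass = mass
  )
}

#' @method tidy cnv_posterior
#' @export
tidy.cnv_posterior <- function(x, n = 4000, mass = 0.95, ...) {
  s <- posterior_sample(x, n)
  h <- marginal_hdi(s, mass)
  tibble(
    parameter = .theta_names,
    estimate = apply(as.matrix(s), 2, median),
    hdi_lower = h$lower,
    hdi_upper = h$upper
  )
}
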
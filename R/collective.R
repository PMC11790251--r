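#' Collective posterior machinery
#'
#' Replicate populations of one strain yield one individual posterior each.
#' The collective posterior conditioned on all n observations is proportional
#' to `P(theta)^(1-n) * prod_i P(theta | X_i)`, evaluated with each individual
#' density floored at `eps` so that a single non-representative observation
#' cannot veto a parameter value supported by the others.
#'
#' @name collective
NULL

# coerce a posterior-like object to a log-density function over point matrices
as_log_density <- function(x) {
  if (inherits(x, "cnv_posterior")) return(function(pts) posterior_logpdf(x, pts))
  if (is.function(x)) return(x)
  abort("posteriors must be cnv_posterior objects or log-density functions")
}

flat_box_log_prior <- function() {
  lv <- log(.box_volume())
  function(pts) ifelse(in_box(pts), -lv, -Inf)
}

#' Unnormalized collective log density
#'
#' Computes `(1 - n) log P(theta) + sum_i log max(eps, P(theta | X_i))`
#' entirely in log space.
#'
#' @param theta Matrix (or vector) of evaluation points.
#' @param posteriors List of `cnv_posterior` objects and/or log-density
#'   functions taking a point matrix.
#' @param log_prior Log prior density function; default: flat over the
#'   three-parameter prior box.
#' @param eps Density floor applied to each individual posterior
#'   (default `exp(-150)`).
#' @return Numeric vector of unnormalized log densities (`-Inf` outside the
#'   prior support).
#' @export
collective_log_density <- function(theta, posteriors,
                                   log_prior = NULL, eps = exp(-150)) {
  stopifnot(length(posteriors) >= 1)
  if (is.null(log_prior)) log_prior <- flat_box_log_prior()
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  n <- length(posteriors)
  lp <- log_prior(theta)
  tot <- (1 - n) * lp
  for (p in posteriors) {
    tot <- tot + pmax(as_log_density(p)(theta), log(eps))
  }
  tot[!is.finite(lp)] <- -Inf
  tot
}

#' Normalize the collective posterior on a dense grid
#'
#' Approximates the normalizing integral of the collective posterior by a
#' Riemann sum over a regular grid (cell midpoints) spanning the prior
#' support — by default 100 points per axis, with the denser 300 per axis
#' available via `resolution`.
#'
#' @inheritParams collective_log_density
#' @param axes Optional list of grid axes (one numeric vector per
#'   coordinate); default: `resolution` midpoints per coordinate of the
#'   three-parameter prior box.
#' @param resolution Grid points per axis when `axes` is `NULL`.
#' @return A `cnv_grid_posterior`: grid axes, normalized log density array,
#'   log normalization constant, and the ingredients for continuous
#'   evaluation.
#' @export
normalize_on_grid <- function(posteriors, axes = NULL, log_prior = NULL,
                              resolution = 100, eps = exp(-150)) {
  if (resolution < 2) abort("`resolution` must be at least 2")
  if (is.null(axes)) {
    axes <- purrr::map2(.theta_lower, .theta_upper, function(lo, hi) {
      h <- (hi - lo) / resolution
      lo + h * (seq_len(resolution) - 0.5)
    })
    names(axes) <- .theta_names
  }
  steps <- vapply(axes, function(a) if (length(a) > 1) a[2] - a[1] else 1,
                  numeric(1))
  cell_volume <- prod(steps)
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  lp <- collective_log_density(grid, posteriors, log_prior, eps)
  m <- max(lp)
  log_norm <- m + log(sum(exp(lp - m))) + log(cell_volume)
  structure(
    list(axes = axes,
         log_density = array(lp - log_norm, dim = lengths(axes)),
         log_norm = log_norm, cell_volume = cell_volume,
         posteriors = posteriors, log_prior = log_prior, eps = eps),
    class = "cnv_grid_posterior"
  )
}

#' @export
print.cnv_grid_posterior <- function(x, ...) {
  cat("<cnv_grid_posterior>\n")
  cat(sprintf("  %s grid over %d coordinate(s), %d individual posterior(s)\n",
              paste(lengths(x$axes), collapse = " x "), length(x$axes),
              length(x$posteriors)))
  invisible(x)
}

#' Collective maximum a posteriori estimate
#'
#' Derivative-free (Nelder-Mead) refinement of the continuous collective
#' density, initialized at the best grid node; falls back to the best grid
#' node (with a warning) if the optimizer does not improve on it.
#'
#' @param grid A `cnv_grid_posterior`.
#' @return One-row tibble with the MAP coordinates and the normalized
#'   `log_density`.
#' @export
collective_map <- function(grid) {
  stopifnot(inherits(grid, "cnv_grid_posterior"))
  ld <- grid$log_density
  best_idx <- arrayInd(which.max(ld), dim(ld))
  start <- vapply(seq_along(grid$axes),
                  function(j) grid$axes[[j]][best_idx[j]], numeric(1))
  lo <- vapply(grid$axes, min, numeric(1))
  hi <- vapply(grid$axes, max, numeric(1))
  f <- function(th) {
    if (any(th < lo | th > hi)) return(1e10)
    -collective_log_density(matrix(th, 1), grid$posteriors, grid$log_prior,
                            grid$eps)
  }
  opt <- tryCatch(
    if (length(start) == 1) {
      optim(start, f, method = "Brent", lower = lo, upper = hi)
    } else {
      optim(start, f, method = "Nelder-Mead",
            control = list(reltol = 1e-10, maxit = 10000))
    },
    error = function(e) NULL)
  v0 <- f(start)
  if (is.null(opt) || opt$value > v0) {
    if (is.null(opt)) warn("optimizer failure; returning best grid node")
    par <- start
  } else {
    par <- opt$par
  }
  nms <- names(grid$axes) %||% paste0("theta", seq_along(par))
  out <- as_tibble(as.list(setNames(par, nms)))
  out$log_density <- -f(par) - grid$log_norm
  out
}

#' Highest-density region of a grid posterior
#'
#' Smallest set of grid cells whose summed probability mass reaches `mass`
#' (cells admitted in order of decreasing density).
#'
#' @param grid A `cnv_grid_posterior`.
#' @param mass Target probability mass (default 0.5).
#' @return Tibble of the selected cells: one column per coordinate, plus
#'   `log_density` and the cell `mass`.
#' @export
hdr <- function(grid, mass = 0.5) {
  stopifnot(inherits(grid, "cnv_grid_posterior"))
  ld <- as.vector(grid$log_density)
  ord <- order(ld, decreasing = TRUE)
  cmass <- cumsum(exp(ld[ord]) * grid$cell_volume)
  k <- which(cmass >= min(mass, cmass[length(cmass)]))[1]
  sel <- ord[seq_len(k)]
  coords <- as_tibble(expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE))[sel, ]
  coords$log_density <- ld[sel]
  coords$mass <- exp(ld[sel]) * grid$cell_volume
  coords
}

#' Marginal density of one coordinate of a grid posterior
#'
#' @param grid A `cnv_grid_posterior`.
#' @param coord Coordinate name or index.
#' @return Tibble with `value` and `density` (normalized in 1D).
#' @export
grid_marginal <- function(grid, coord) {
  stopifnot(inherits(grid, "cnv_grid_posterior"))
  j <- if (is.character(coord)) match(coord, names(grid$axes)) else coord
  dens <- apply(exp(grid$log_density), j, sum) *
    grid$cell_volume / (grid$axes[[j]][2] - grid$axes[[j]][1])
  tibble(value = grid$axes[[j]], density = dens)
}

# shortest interval covering `mass` of a gridded 1-D density
grid_hdi <- function(marginal, mass = 0.95) {
  h <- marginal$value[2] - marginal$value[1]
  ord <- order(marginal$density, decreasing = TRUE)
  cmass <- cumsum(marginal$density[ord] * h)
  k <- which(cmass >= min(mass, cmass[length(cmass)]))[1]
  range(marginal$value[ord[seq_len(k)]])
}

#' @method tidy cnv_grid_posterior
#' @export
tidy.cnv_grid_posterior <- function(x, mass = 0.5, ...) {
  map <- collective_map(x)
  nms <- names(x$axes)
  purrr::map_dfr(seq_along(nms), function(j) {
    h <- grid_hdi(grid_marginal(x, j), mass)
    tibble(parameter = nms[j], map = map[[nms[j]]],
           hdi_lower = h[1], hdi_upper = h[2], mass = mass)
  })
}
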
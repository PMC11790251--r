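#' Plot CNV proportion trajectories
#'
#' One line per population; reported proportions solid, total (when present)
#' dashed.
#'
#' @param data Observation tibble (`population`, `generation`,
#'   `prop_reported`, optional `prop_total`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$generation,
                                          .data$prop_reported,
                                          group = .data$population,
                                          colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "CNV proportion",
                  colour = "Population") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if ("prop_total" %in% names(data) && any(is.finite(data$prop_total))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$prop_total),
                                linetype = "dashed")
  }
  p
}

#' Heatmap of a 2-D marginal of a grid posterior with the collective MAP
#'
#' @param object A `cnv_grid_posterior`.
#' @param coords Two coordinate names to display (default formation rate vs
#'   selection coefficient).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cnv_grid_posterior
#' @export
autoplot.cnv_grid_posterior <- function(object,
                                        coords = c("log10_dC", "log10_sC"),
                                        ...) {
  j <- match(coords, names(object$axes))
  dens <- apply(exp(object$log_density), j, sum)
  df <- expand.grid(x = object$axes[[j[1]]], y = object$axes[[j[2]]])
  df$density <- as.vector(dens)
  map <- collective_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(
      data = data.frame(x = map[[coords[1]]], y = map[[coords[2]]]),
      ggplot2::aes(.data$x, .data$y), fill = NA, colour = "black",
      shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = coords[1], y = coords[2], fill = "density") +
    ggplot2::theme_minimal()
}

#' Mean strain-proportion trajectories of a competition simulation
#'
#' @param object A `cnv_competition`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cnv_competition
#' @export
autoplot.cnv_competition <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trajectory, -"generation",
                            names_to = "strain", values_to = "proportion")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$proportion,
                                   colour = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Mean strain proportion") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a predicted diversity trajectory
#'
#' @param data Tibble from [diversity_trajectory()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$generation, .data$diversity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Generation",
                  y = "Shannon diversity (effective lineages)") +
    ggplot2::theme_minimal()
}
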
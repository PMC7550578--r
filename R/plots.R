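#' Plot a tissue state
#'
#' Draws every cell polygon colored by class. Cells wrapping around the
#' periodic boundary are drawn unwrapped from their first vertex.
#'
#' @param object a `corti_tissue`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot corti_tissue
#' @export
autoplot.corti_tissue <- function(object, ...) {
  g <- tissue_geometry(object)
  sl <- tissue_slots(object)
  px0 <- object$pos[sl$v[sl$starts], 1]
  py0 <- object$pos[sl$v[sl$starts], 2]
  df <- tibble::tibble(
    x = g$ux + rep.int(px0, sl$k),
    y = g$uy + rep.int(py0, sl$k),
    cell = sl$cell,
    class = object$class[sl$cell])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$cell,
                                   fill = .data$class)) +
    ggplot2::geom_polygon(color = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(
      HC = "#4f8fdd", SC = "#e98a8a", pillar = "#8a67ab", IHC = "#2b5fa8",
      top_boundary = "#c7b45e", outside = "grey85")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}

#' Plot the metric series of a trajectory
#'
#' Order parameters versus simulation step: mean SC-neighbor count, mean
#' stretch-corrected hexagonal order, HC/SC area ratio and hair-cell
#' count, as facets.
#'
#' @param object a `corti_trajectory` run with metrics.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot corti_trajectory
#' @export
autoplot.corti_trajectory <- function(object, ...) {
  m <- tidy(object)
  long <- tidyr::pivot_longer(
    m[, c("step", "mean_sc_neighbors", "mean_psi6_star", "area_ratio",
          "n_hc")],
    -"step", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line(color = "#4f8fdd") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "simulation step", y = NULL)
}

#' Plot a structure factor grid
#'
#' @param sf tibble from [structure_factor()].
#' @param cap cap S values for display (default 98th percentile).
#' @return a ggplot object.
#' @export
plot_structure_factor <- function(sf, cap = stats::quantile(sf$S, 0.98)) {
  sf$S <- pmin(sf$S, cap)
  ggplot2::ggplot(sf, ggplot2::aes(.data$qx, .data$qy, fill = .data$S)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "q_x", y = "q_y", fill = "S(q)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
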
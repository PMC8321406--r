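#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_path
#'   geom_tile geom_col geom_line scale_fill_viridis_c scale_color_viridis_c
#'   labs theme_minimal facet_wrap coord_equal geom_contour
NULL

#' @export
ggplot2::autoplot

#' Plot a traced neuron over its image
#'
#' @param trace A `pvd_trace`.
#' @param image Optional background image matrix.
#' @param color_by `"class"` (if classified), `"segment"`, or `"score"`.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, image = NULL, color_by = c("class", "segment", "score")) {
  color_by <- match.arg(color_by)
  el <- trace$elements
  if (!is.null(trace$coords) && color_by == "class" &&
      !is.null(trace$coords$class)) {
    el <- el |> left_join(trace$coords |> select("id", "class"), by = "id")
    el$colv <- factor(el$class)
  } else if (color_by == "score") {
    el$colv <- el$score
  } else {
    el$colv <- factor(el$segment %% 8)
  }
  p <- ggplot()
  if (!is.null(image)) {
    df <- tibble(
      x = rep(seq_len(ncol(image)), each = nrow(image)),
      y = rep(seq_len(nrow(image)), times = ncol(image)),
      v = as.vector(image)
    )
    p <- p + geom_raster(data = df, aes(x = .data$x, y = .data$y,
                                        fill = .data$v)) +
      scale_fill_viridis_c(option = "magma", guide = "none")
  }
  p +
    geom_point(data = el, aes(x = .data$x, y = .data$y,
                              color = .data$colv), size = 0.4) +
    geom_point(data = trace$junctions, aes(x = .data$x, y = .data$y),
               shape = 1, color = "white", size = 2) +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(color = color_by, x = "x (px)", y = "y (px)") +
    theme_minimal()
}

#' @export
autoplot.junction_mc_fit <- function(object, ...) {
  surf <- object$sigma_surface
  ggplot(surf, aes(x = .data$alpha1, y = .data$alpha2,
                   fill = .data$residual)) +
    geom_tile() +
    scale_fill_viridis_c(trans = "log10") +
    geom_point(data = object$best, color = "red", shape = 4, size = 3) +
    labs(x = expression(alpha[1] ~ "(deg)"), y = expression(alpha[2] ~ "(deg)"),
         fill = "residual",
         title = "Junction-configuration fit residual (best sigma per cell)") +
    theme_minimal()
}

#' @export
autoplot.pvd_class_model <- function(object, ...) {
  df <- tibble(
    theta = rep(object$theta_grid, times = length(object$aphi_grid)),
    aphi = rep(object$aphi_grid, each = length(object$theta_grid)),
    density = as.vector(object$density),
    class = factor(as.vector(object$class_map))
  )
  ggplot(df, aes(x = .data$theta, y = .data$aphi)) +
    geom_tile(aes(fill = .data$class), alpha = 0.35) +
    geom_contour(aes(z = .data$density), color = "grey30", bins = 8) +
    geom_point(data = object$modes, aes(x = .data$theta, y = .data$aphi),
               shape = 4, size = 3) +
    labs(x = expression(theta ~ "(deg)"), y = expression("|" * phi * "| (deg)"),
         fill = "class",
         title = "Element density and morphological classes") +
    theme_minimal()
}

#' @export
autoplot.pvd_morphometry <- function(object, ...) {
  pc <- object$per_class |>
    select("class", "length_pct", "junction_density_per_100um",
           "tip_density_per_100um", "mean_curvature") |>
    tidyr::pivot_longer(-"class", names_to = "metric")
  ggplot(pc, aes(x = factor(.data$class), y = .data$value,
                 fill = factor(.data$class))) +
    geom_col() +
    facet_wrap(~ .data$metric, scales = "free_y") +
    labs(x = "morphological class", y = NULL, fill = "class") +
    theme_minimal()
}

#' Azimuth and orientation histograms of a cohort
#'
#' @param coords Pooled `coords` tibble(s).
#' @param bin Bin width in degrees.
#' @return A ggplot object with the signed azimuth distribution.
#' @export
plot_azimuth_distribution <- function(coords, bin = 2) {
  df <- coords |> filter(!is.na(.data$phi))
  ggplot(df, aes(x = .data$phi)) +
    ggplot2::geom_histogram(binwidth = bin, boundary = 0,
                            fill = "steelblue", color = NA) +
    labs(x = expression(phi ~ "(deg, dorsal positive)"), y = "elements",
         title = "Azimuthal distribution of dendritic elements") +
    theme_minimal()
}
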
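#' Plot a radial distribution function profile
#'
#' Line-and-point plot of g against shell index, with the g = 1 random-
#' placement baseline and, for 8-shell profiles, the functional regions
#' of the secretory pathway shaded in the background.
#'
#' @param object An `sxt_rdf` tibble.
#' @param shade_regions Shade functional regions (8-shell profiles only).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sxt_rdf <- function(object, shade_regions = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$shell, y = .data$g))
  if (shade_regions && nrow(object) == 8L) {
    bands <- tibble::tibble(
      xmin = c(0.5, 1.5, 3.5, 6.5), xmax = c(1.5, 3.5, 6.5, 8.5),
      region = c("perinuclear", "maturation", "transportation", "secretion"))
    p <- p + ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf,
                   ymax = Inf, fill = .data$region))
  }
  p +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$shell) +
    ggplot2::labs(x = "cytosol shell (1 = perinuclear)", y = "g",
                  title = paste("RDF:", attr(object, "population")),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a radial LAC profile
#'
#' @param object An `sxt_lacprofile` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sxt_lacprofile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin, y = .data$mean_lac)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance from instance boundary (voxels)",
                  y = "mean LAC (1/µm)") +
    ggplot2::theme_minimal()
}

#' Plot one X orthoslice of a cell scene
#'
#' @param scene A [cell_scene()].
#' @param x Slice index along X.
#' @return A ggplot raster of the slice with one color per class.
#' @export
plot_scene_slice <- function(scene, x = round(dim(scene)[1] / 2)) {
  check_dim3(scene, "scene")
  sl <- scene[x, , ]
  df <- expand.grid(y = seq_len(nrow(sl)), z = seq_len(ncol(sl)))
  df$class <- factor(names(scene_codes())[as.integer(sl) + 1L],
                     levels = names(scene_codes()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$z,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      outside = "grey95", cytoplasm = "wheat", mitochondria = "firebrick",
      nucleus = "steelblue", vesicle = "darkgreen"), drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Y (voxels)", y = "Z (voxels)",
                  title = paste("scene slice X =", x)) +
    ggplot2::theme_minimal()
}
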
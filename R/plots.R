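#' Plot methods
#'
#' `autoplot()` methods render the package's main objects with ggplot2:
#' rasters as filled cell maps (log10 colour scale for current density,
#' where pinch points span orders of magnitude), scenario sensitivity as a
#' correlation heat map, and case model fits as observed-available
#' prediction lines across displacement distance.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.omc_raster <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (inherits(object, "omc_current_map")) {
    p <- p + ggplot2::scale_fill_viridis_c(
      trans = "log10", na.value = "grey80", name = "current (A)")
  } else if (inherits(object, "omc_category_raster")) {
    p <- p + ggplot2::scale_fill_viridis_c(na.value = "grey80",
                                           name = "category")
  } else {
    p <- p + ggplot2::scale_fill_viridis_c(na.value = "grey80", name = "cost")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.omc_raster
#' @export
autoplot.omc_sensitivity <- function(object, ...) {
  nm <- rownames(object$rho)
  df <- tidyr::expand_grid(a = nm, b = nm)
  df$rho <- as.vector(t(object$rho))
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1), name = "Spearman rho") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname autoplot.omc_raster
#' @param d_range Displacement range over which to draw predictions
#'   (defaults to 0 to the largest observed `d_max` is not known here, so
#'   0..1 scaled units).
#' @export
autoplot.omc_model_fit <- function(object, d_range = c(0, 1), ...) {
  co <- object$coefficients
  get <- function(term) {
    v <- co$estimate[co$term == term]
    if (length(v)) v else 0
  }
  d <- seq(d_range[1], d_range[2], length.out = 50)
  df <- dplyr::bind_rows(
    tibble::tibble(d_max = d, which = "available",
                   value = get("(Intercept)") + get("d_max") * d),
    tibble::tibble(d_max = d, which = "observed",
                   value = get("(Intercept)") + get("case") +
                     (get("d_max") + get("case:d_max")) * d)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$d_max, .data$value,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "maximum displacement distance",
                  y = "predicted current density", colour = NULL)
}
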
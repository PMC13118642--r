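#' Response-surface plot
#'
#' Filled-contour plot of a fitted two-factor surface over the coded design
#' region, drawn in actual units, with the design points overlaid. One-factor
#' fits are drawn as a prediction curve over the factor range.
#'
#' @param object A `surface_fit`.
#' @param n Grid resolution per axis (default 101).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot surface_fit
#' @export
autoplot.surface_fit <- function(object, n = 101, ...) {
  ftab <- object$factors
  alpha <- object$alpha
  if (nrow(ftab) == 1L) {
    f <- ftab[1, ]
    x <- decode_value(seq(-alpha, alpha, length.out = n), f)
    nd <- tibble::tibble(!!f$name := x)
    nd$.pred <- as.vector(suppressWarnings(predict(object, nd)))
    return(
      ggplot2::ggplot(nd, ggplot2::aes(x = .data[[f$name]], y = .data$.pred)) +
        ggplot2::geom_line(linewidth = 0.8) +
        ggplot2::geom_point(data = object$data,
                            ggplot2::aes(x = .data[[f$name]], y = .data$.y)) +
        ggplot2::labs(x = axis_lab(f), y = object$response,
                      title = sprintf("%s (%s model)", object$response,
                                      object$model_class)) +
        ggplot2::theme_minimal()
    )
  }
  if (nrow(ftab) != 2L) {
    stop("autoplot supports 1- or 2-factor surfaces.", call. = FALSE)
  }
  g1 <- decode_value(seq(-alpha, alpha, length.out = n), ftab[1, ])
  g2 <- decode_value(seq(-alpha, alpha, length.out = n), ftab[2, ])
  grid <- tidyr::expand_grid(!!ftab$name[1] := g1, !!ftab$name[2] := g2)
  grid$.pred <- as.vector(suppressWarnings(predict(object, grid)))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[ftab$name[1]]],
                                     y = .data[[ftab$name[2]]])) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$.pred)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$.pred), colour = "white",
                          alpha = 0.6) +
    ggplot2::geom_point(data = object$data, colour = "black", size = 1.5) +
    ggplot2::scale_fill_viridis_c(name = object$response) +
    ggplot2::labs(x = axis_lab(ftab[1, ]), y = axis_lab(ftab[2, ]),
                  title = sprintf("%s (%s model)", object$response,
                                  object$model_class)) +
    ggplot2::theme_minimal()
}

axis_lab <- function(f) {
  if (!is.na(f$unit) && nzchar(f$unit)) paste0(f$name, " (", f$unit, ")") else f$name
}

#' Plot a cumulative release profile
#'
#' @param release Output of [cumulative_release()] (or any tibble with
#'   `time_h` and `cumulative_pct`), optionally with a grouping column.
#' @param group Optional column name for multiple profiles.
#' @return A ggplot object.
#' @export
plot_release_profile <- function(release, group = NULL) {
  p <- ggplot2::ggplot(release, ggplot2::aes(x = .data$time_h,
                                             y = .data$cumulative_pct))
  if (!is.null(group)) {
    p <- p + ggplot2::aes(colour = .data[[group]], group = .data[[group]])
  }
  p +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (h)", y = "Cumulative release (%)") +
    ggplot2::theme_minimal()
}

#' Plot a plasma concentration-time profile
#'
#' @param profile Tibble with `time_h`, `conc` and optionally `sem` columns
#'   (e.g. from [sim_pk_profile()]).
#' @param group Optional column name for multiple profiles.
#' @return A ggplot object.
#' @export
plot_pk_profile <- function(profile, group = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$time_h, y = .data$conc))
  if (!is.null(group)) {
    p <- p + ggplot2::aes(colour = .data[[group]], group = .data[[group]])
  }
  if ("sem" %in% names(profile)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conc - .data$sem, ymax = .data$conc + .data$sem),
      width = 0.2, alpha = 0.6
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time post-dose (h)", y = "Concentration") +
    ggplot2::theme_minimal()
}
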